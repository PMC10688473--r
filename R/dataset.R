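#' Sample putatively neutral variants per gene
#'
#' For each gene carrying labelled pathogenic variants, draws population
#' variants from the supplied candidate pool to serve as the neutral class:
#' a minimum of two and up to the count of the least-represented labelled
#' class in that gene (`max(2, min(n_GOF, n_LOF))`, classes with zero
#' variants ignored), capped by pool availability. Sampling is uniform
#' without replacement. Candidate pools are assumed pre-filtered of known
#' pathogenic variants.
#'
#' @param per_gene_counts Tibble with columns `gene`, `n_gof`, `n_lof`.
#' @param pool Tibble of candidate variants with at least a `gene` column.
#' @return Tibble of sampled pool rows with `label = "NEUTRAL"`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene = "G1", n_gof = 10, n_lof = 4)
#' pool <- tibble::tibble(gene = rep("G1", 20), variant_id = paste0("v", 1:20))
#' nrow(sample_neutral(counts, pool)) # 4
sample_neutral <- function(per_gene_counts, pool) {
  out <- lapply(seq_len(nrow(per_gene_counts)), function(i) {
    g <- per_gene_counts$gene[i]
    counts <- c(per_gene_counts$n_gof[i], per_gene_counts$n_lof[i])
    counts <- counts[counts > 0]
    if (length(counts) == 0) return(NULL)
    target <- max(2L, min(counts))
    cand <- pool[pool$gene == g, , drop = FALSE]
    if (nrow(cand) == 0) {
      warning("no candidate pool for gene ", g, "; gene skipped",
              call. = FALSE)
      return(NULL)
    }
    take <- min(target, nrow(cand))
    cand[sample.int(nrow(cand), take), , drop = FALSE]
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) res$label <- "NEUTRAL"
  res
}

#' Label-stratified, gene-disjoint train/test split
#'
#' Assigns whole genes to the training or testing partition so that (a) the
#' training partition holds approximately `train_fraction` of all variants
#' and (b) the per-class composition of each partition reflects the full
#' dataset, with gene-disjointness as a hard constraint. The assignment is
#' a greedy bin-packing pass (largest genes first, each gene sent to the
#' partition with the larger remaining deficit) repeated over random
#' restarts, keeping the assignment with the best stratification score.
#'
#' @param variants Tibble with columns `gene` and `label`.
#' @param train_fraction Target training share of variants.
#' @param restarts Number of random restarts.
#' @return Object of class `split_result`: tibbles `train` and `test`,
#'   `gene_assignment` (gene -> "train"/"test"), `score`, and the achieved
#'   `train_share`.
#' @export
split_by_gene <- function(variants, train_fraction = 0.9, restarts = 1000L) {
  abort_if(!all(c("gene", "label") %in% names(variants)),
           "`variants` needs gene and label columns")
  abort_if(train_fraction <= 0 || train_fraction >= 1,
           "`train_fraction` must be in (0, 1)")
  classes <- sort(unique(variants$label))
  gene_class <- table(variants$gene, variants$label)
  genes <- rownames(gene_class)
  gc_mat <- matrix(as.numeric(gene_class), nrow = length(genes),
                   dimnames = dimnames(gene_class))
  totals <- colSums(gc_mat)
  target <- totals * train_fraction
  gene_sizes <- rowSums(gc_mat)

  score_of <- function(train_counts) {
    # deviation of per-class train shares and the overall share
    shares <- ifelse(totals > 0, train_counts / totals, train_fraction)
    sum(abs(shares - train_fraction)) +
      abs(sum(train_counts) / sum(totals) - train_fraction)
  }

  best <- NULL
  best_score <- Inf
  for (r in seq_len(restarts)) {
    ord <- order(gene_sizes + runif(length(genes)), decreasing = TRUE)
    train_counts <- setNames(numeric(length(classes)), classes)
    assign_train <- logical(length(genes))
    for (gi in ord) {
      with_g <- train_counts + gc_mat[gi, ]
      # deficit-driven greedy: add the gene to train while train is under
      # target, otherwise leave it to test
      if (score_of(with_g) <= score_of(train_counts)) {
        train_counts <- with_g
        assign_train[gi] <- TRUE
      }
    }
    sc <- score_of(train_counts)
    if (sc < best_score) {
      best_score <- sc
      best <- assign_train
    }
  }
  assignment <- setNames(ifelse(best, "train", "test"), genes)
  in_train <- variants$gene %in% genes[best]
  structure(
    list(
      train = variants[in_train, , drop = FALSE],
      test = variants[!in_train, , drop = FALSE],
      gene_assignment = assignment,
      score = best_score,
      train_share = mean(in_train)
    ),
    class = "split_result"
  )
}

#' @method print split_result
#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> %d train / %d test variants (train share %.1f%%), %d genes\n",
    nrow(x$train), nrow(x$test), 100 * x$train_share,
    length(x$gene_assignment)))
  invisible(x)
}

#' @method glance split_result
#' @export
glance.split_result <- function(x, ...) {
  all_labels <- c(x$train$label, x$test$label)
  per_class <- vapply(sort(unique(all_labels)), function(cl) {
    sum(x$train$label == cl) / sum(all_labels == cl)
  }, numeric(1))
  tibble::tibble(
    n_train = nrow(x$train), n_test = nrow(x$test),
    train_share = x$train_share, score = x$score,
    class = names(per_class), class_train_share = unname(per_class)
  )
}

#' Greedy homology clustering at an identity threshold
#'
#' Clusters protein sequences so that members of different clusters share
#' no more than `identity_threshold` identity: sequences are sorted by
#' length (longest first) and each joins the first existing cluster whose
#' representative it matches at or above the threshold, otherwise it founds
#' a new cluster. Identity is `matches / alignment length` of a BLOSUM62-
#' scored global alignment with affine gaps (the semantics of the usual
#' clustering tools, without their word-filter heuristics — exact alignment
#' is affordable at this scale).
#'
#' @param sequences Named character vector of amino-acid sequences
#'   (uppercase 20-letter alphabet, `X` allowed).
#' @param identity_threshold Join threshold in (0, 1]; default 0.4.
#' @return Object of class `homology_clustering`: tibble `members`
#'   (`protein`, `cluster`, `representative`), and `representatives`
#'   (cluster -> founding protein).
#' @export
cluster_homologs <- function(sequences, identity_threshold = 0.4) {
  abort_if(length(sequences) == 0, "no sequences supplied")
  abort_if(is.null(names(sequences)), "`sequences` must be named")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  ord <- order(nchar(sequences), decreasing = TRUE)
  reps <- character(0)
  cluster_of <- setNames(integer(length(sequences)), names(sequences))
  for (i in ord) {
    s <- sequences[i]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      pid <- alignment_identity(sequences[[reps[ci]]], s[[1]])
      if (pid >= identity_threshold) {
        cluster_of[names(s)] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(s))
      cluster_of[names(s)] <- length(reps)
    }
  }
  structure(
    list(
      members = tibble::tibble(
        protein = names(cluster_of),
        cluster = unname(cluster_of),
        representative = reps[cluster_of]
      ),
      representatives = reps
    ),
    class = "homology_clustering"
  )
}

#' Global alignment identity between two sequences
#'
#' Identity = matches / alignment length (gap columns included) of a
#' BLOSUM62-scored Needleman-Wunsch alignment with affine gap penalties.
#'
#' @param a,b Amino-acid strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Identity in `[0, 1]`.
#' @export
alignment_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = get("BLOSUM62"), type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  # PID1: 100 * matches / (aligned positions + internal gap positions)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Enforce homology disjointness on a split
#'
#' Within each homology cluster, keeps variants only from the cluster
#' member with the greatest number of labelled variants (ties broken in
#' favour of the cluster representative, then alphabetically), and drops
#' test-set variants whose cluster also contributes variants to the
#' training set.
#'
#' @param split A [split_by_gene()] result whose variant tables carry a
#'   `protein` column.
#' @param clustering A [cluster_homologs()] result.
#' @return A filtered `split_result`.
#' @export
apply_homology_filter <- function(split, clustering) {
  members <- clustering$members
  all_vars <- dplyr::bind_rows(
    dplyr::mutate(split$train, .partition = "train"),
    dplyr::mutate(split$test, .partition = "test")
  )
  abort_if(!"protein" %in% names(all_vars),
           "split variant tables need a `protein` column")
  all_vars <- dplyr::left_join(all_vars, members, by = "protein")
  # proteins absent from the clustering each form their own cluster
  miss <- is.na(all_vars$cluster)
  if (any(miss)) {
    extra <- match(all_vars$protein[miss], unique(all_vars$protein[miss]))
    all_vars$cluster[miss] <- max(members$cluster, 0L) + extra
    all_vars$representative[miss] <- all_vars$protein[miss]
  }
  keep_protein <- all_vars |>
    dplyr::count(.data$cluster, .data$protein, .data$representative) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$n),
                   .data$protein != .data$representative,
                   .data$protein, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  kept <- dplyr::semi_join(all_vars, keep_protein,
                           by = c("cluster", "protein"))
  train_clusters <- unique(kept$cluster[kept$.partition == "train"])
  kept <- kept[!(kept$.partition == "test" &
                   kept$cluster %in% train_clusters), , drop = FALSE]
  drop_cols <- c(".partition", "cluster", "representative")
  structure(
    list(
      train = kept[kept$.partition == "train",
                   setdiff(names(kept), drop_cols), drop = FALSE],
      test = kept[kept$.partition == "test",
                  setdiff(names(kept), drop_cols), drop = FALSE],
      gene_assignment = split$gene_assignment,
      score = split$score,
      train_share = NA_real_
    ),
    class = "split_result"
  )
}
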