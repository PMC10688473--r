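#' Specification for a synthetic variant/feature dataset
#'
#' Bundles the parameters of the synthetic labelled-variant generator: how
#' many genes and variants to simulate, the GOF/LOF/neutral class mix, how
#' many informative and pure-noise feature columns to emit, the
#' class-conditional effect size (mean shift in SD units), and the rate at
#' which feature values are masked as missing.
#'
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @param n_genes Number of genes.
#' @param variants_per_gene Variants simulated per gene.
#' @param class_mix Length-3 vector of GOF/LOF/neutral proportions summing
#'   to 1.
#' @param n_informative Number of informative feature columns (class-shifted
#'   distributions; every fourth one is categorical with class-dependent
#'   category frequencies).
#' @param effect_size Class-conditional mean shift, in units of the
#'   within-class standard deviation. `0` produces a null dataset on which a
#'   classifier can only reach chance performance.
#' @param n_noise Number of class-independent noise features.
#' @param missing_rate Proportion of feature cells masked `NA`, in `[0, 1)`.
#'
#' @return An object of class `synthetic_spec` (a named list).
#' @export
#' @examples
#' synthetic_spec(seed = 1, n_genes = 20, variants_per_gene = 5)
synthetic_spec <- function(seed = 1L,
                           n_genes = 300L,
                           variants_per_gene = 10L,
                           class_mix = c(GOF = 0.05, LOF = 0.475, NEUTRAL = 0.475),
                           n_informative = 6L,
                           effect_size = 2,
                           n_noise = 10L,
                           missing_rate = 0.05) {
  abort_if(length(class_mix) != 3L, "`class_mix` must have length 3")
  abort_if(any(class_mix < 0) || any(class_mix > 1),
           "`class_mix` proportions must lie in [0, 1]")
  abort_if(abs(sum(class_mix) - 1) > 1e-9, "`class_mix` must sum to 1")
  abort_if(n_genes < 1 || variants_per_gene < 1, "counts must be positive")
  abort_if(n_informative < 0 || n_noise < 0, "feature counts must be >= 0")
  abort_if(missing_rate < 0 || missing_rate >= 1,
           "`missing_rate` must be in [0, 1)")
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      variants_per_gene = as.integer(variants_per_gene),
      class_mix = setNames(as.numeric(class_mix), c("GOF", "LOF", "NEUTRAL")),
      n_informative = as.integer(n_informative),
      effect_size = as.numeric(effect_size),
      n_noise = as.integer(n_noise),
      missing_rate = as.numeric(missing_rate)
    ),
    class = "synthetic_spec"
  )
}

#' Simulate a labelled variant table with known informative features
#'
#' Draws variant labels i.i.d. from the class mix, then generates feature
#' columns: informative features are class-shifted (Gaussian with per-class
#' means separated by `effect_size` SD units, or categorical with
#' class-dependent category frequencies), noise features are
#' class-independent. Missing values are injected completely at random at
#' the spec's `missing_rate`. Ground truth (the informative feature names)
#' is returned alongside the data so recovery can be tested.
#'
#' @param spec A [synthetic_spec()].
#'
#' @return A list with elements `variants` (tibble: `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `protein`, `residue_index`, `label`),
#'   `features` (tibble: `variant_id` plus feature columns), and
#'   `informative` (character vector of informative column names).
#' @export
#' @examples
#' sim <- sim_variant_dataset(synthetic_spec(seed = 1, n_genes = 10))
#' table(sim$variants$label)
sim_variant_dataset <- function(spec) {
  abort_if(!inherits(spec, "synthetic_spec"),
           "`spec` must be created by synthetic_spec()")
  withr::with_seed(spec$seed, {
    n <- spec$n_genes * spec$variants_per_gene
    genes <- rep(sprintf("GENE%04d", seq_len(spec$n_genes)),
                 each = spec$variants_per_gene)
    classes <- c("GOF", "LOF", "NEUTRAL")
    label <- sample(classes, n, replace = TRUE, prob = spec$class_mix)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    variants <- tibble::tibble(
      variant_id = sprintf("v%05d", seq_len(n)),
      chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
      pos = sample.int(2e8, n, replace = TRUE),
      ref = ref, alt = unname(alt),
      gene = genes,
      protein = sub("GENE", "PROT", genes),
      residue_index = sample.int(500L, n, replace = TRUE),
      label = label
    )

    cls_idx <- match(label, classes)
    feat <- list(variant_id = variants$variant_id)
    informative <- character(0)
    for (j in seq_len(spec$n_informative)) {
      nm <- sprintf("inf_%02d", j)
      informative <- c(informative, nm)
      if (j %% 4L == 0L) {
        # categorical informative: class-dependent category frequencies,
        # interpolated towards uniform as the effect size shrinks so that
        # effect_size = 0 yields a true null dataset
        skew <- rbind(c(.7, .2, .1), c(.2, .6, .2), c(.1, .2, .7))
        w <- min(spec$effect_size / 2, 1)
        probs <- w * skew + (1 - w) * matrix(1 / 3, 3, 3)
        feat[[nm]] <- vapply(cls_idx, function(k) {
          sample(c("low", "mid", "high"), 1L, prob = probs[k, ])
        }, character(1))
      } else {
        sgn <- if (j %% 2L == 0L) -1 else 1
        mu <- sgn * spec$effect_size * (cls_idx - 2L)
        feat[[nm]] <- rnorm(n, mean = mu, sd = 1)
      }
    }
    for (j in seq_len(spec$n_noise)) {
      feat[[sprintf("noise_%02d", j)]] <- rnorm(n)
    }
    features <- tibble::as_tibble(feat)

    if (spec$missing_rate > 0) {
      for (nm in setdiff(names(features), "variant_id")) {
        drop <- runif(n) < spec$missing_rate
        features[[nm]][drop] <- NA
      }
    }
    list(variants = variants, features = features, informative = informative)
  })
}

#' Simulate a self-avoiding CA-trace protein structure in PDB format
#'
#' Builds a random 3D walk with a fixed 3.8 Angstrom step between
#' consecutive alpha-carbons and a 3.0 Angstrom self-avoidance radius, adds
#' one CB-like side-chain atom per residue, and fills the B-factor column
#' with per-residue confidence values in `[0, 100]` (the convention used by
#' predicted-structure models). No force field is involved; the geometry is
#' only meant to exercise distance-based feature code.
#'
#' @param n_residues Number of residues (>= 1).
#' @param seed Integer seed.
#' @param compact If `TRUE`, bias the walk back towards the origin so the
#'   chain forms a globule (useful for burial tests); default `FALSE`.
#'
#' @return A single string of PDB `ATOM` records terminated by `END`.
#' @export
#' @examples
#' pdb <- sim_structure(10, seed = 1)
#' model <- read_structure(text = pdb)
sim_structure <- function(n_residues, seed = 1L, compact = FALSE) {
  abort_if(n_residues < 1, "`n_residues` must be >= 1")
  withr::with_seed(as.integer(seed), {
    step <- 3.8
    avoid <- 3.0
    ca <- matrix(NA_real_, n_residues, 3)
    ca[1, ] <- c(0, 0, 0)
    for (i in seq_len(n_residues)[-1]) {
      placed <- FALSE
      for (try in 1:500) {
        d <- rnorm(3)
        if (compact && sqrt(sum(ca[i - 1, ]^2)) > 2 * n_residues^(1 / 3)) {
          d <- d - 0.8 * ca[i - 1, ] / sqrt(sum(ca[i - 1, ]^2))
        }
        cand <- ca[i - 1, ] + step * d / sqrt(sum(d^2))
        prev <- ca[seq_len(i - 2L), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= avoid) {
          ca[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      abort_if(!placed, "self-avoiding walk failed; try another seed")
    }
    resnames <- sample(AA3, n_residues, replace = TRUE)
    plddt <- round(runif(n_residues, 0, 100), 2)
    lines <- character(0)
    serial <- 0L
    for (i in seq_len(n_residues)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "CA", resnames[i], i,
                                      ca[i, ], plddt[i], "C"))
      # CB-like side-chain atom 1.5 A away in a random direction
      d <- rnorm(3)
      cb <- ca[i, ] + 1.5 * d / sqrt(sum(d^2))
      serial <- serial + 1L
      atom <- if (resnames[i] == "GLY") "O" else "CB"
      elem <- if (resnames[i] == "GLY") "O" else "C"
      lines <- c(lines, pdb_atom_line(serial, atom, resnames[i], i,
                                      cb, plddt[i], elem))
    }
    paste0(paste(lines, collapse = "\n"), "\nEND\n")
  })
}

# one fixed-column PDB ATOM record
pdb_atom_line <- function(serial, atom, resname, resno, xyz, bfac, element) {
  sprintf(
    "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, atom, resname, resno, xyz[1], xyz[2], xyz[3], 1.00, bfac, element
  )
}

#' Simulate a publication corpus with planted GOF/LOF phrases
#'
#' Generates title/abstract documents according to a per-document phrase
#' plan. Documents planned `GOF` or `LOF` embed exactly one matching phrase
#' (random casing, random surface form from the pattern list); `both`
#' documents embed one of each; `none` documents contain only decoy strings
#' ("functional gain", "lost function") that a correct matcher must not hit.
#'
#' @param phrase_plan Character vector over `{"GOF", "LOF", "both", "none"}`,
#'   one entry per document.
#' @param seed Integer seed.
#'
#' @return A list with `docs` (tibble: `id`, `title`, `abstract`) and
#'   `plan` (the input plan). `write_corpus_jsonl()` serializes `docs`.
#' @export
#' @examples
#' sim_corpus(c("GOF", "none"), seed = 3)$docs
sim_corpus <- function(phrase_plan, seed = 1L) {
  abort_if(length(phrase_plan) < 1, "`phrase_plan` must be nonempty")
  bad <- setdiff(phrase_plan, c("GOF", "LOF", "both", "none"))
  abort_if(length(bad) > 0,
           paste0("unknown plan token(s): ", paste(bad, collapse = ", ")))
  filler <- c(
    "We studied a missense substitution in a large pedigree.",
    "Electrophysiology revealed altered channel kinetics.",
    "Patient fibroblasts were assayed for enzymatic activity.",
    "Structural modelling suggested a destabilised interface.",
    "Expression in heterologous cells confirmed the phenotype."
  )
  decoys <- c("A functional gain was recorded in treated cells.",
              "The lost function could not be restored by chaperones.")
  randcase <- function(s) {
    ch <- strsplit(s, "")[[1]]
    flip <- runif(length(ch)) < 0.3
    ch[flip] <- toupper(ch[flip])
    paste(ch, collapse = "")
  }
  pat <- gof_lof_patterns()
  withr::with_seed(as.integer(seed), {
    docs <- purrr::imap(phrase_plan, function(plan, i) {
      mk <- function(class) {
        phr <- sample(pat$pattern[pat$class == class], 1L)
        randcase(sprintf("This variant shows a %s effect in vitro.", phr))
      }
      body <- sample(filler, 3L)
      extra <- switch(plan,
        GOF = mk("GOF"),
        LOF = mk("LOF"),
        both = paste(mk("GOF"), mk("LOF")),
        none = sample(decoys, 1L)
      )
      tibble::tibble(
        id = sprintf("PMID%06d", i),
        title = body[1],
        abstract = paste(c(body[-1], extra), collapse = " ")
      )
    })
    list(docs = dplyr::bind_rows(docs), plan = phrase_plan)
  })
}

#' Write / read a JSONL publication corpus
#'
#' One JSON object per line with fields `id`, `title`, `abstract`.
#'
#' @param docs Tibble with columns `id`, `title`, `abstract`.
#' @param path File path.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns the docs tibble.
#' @export
write_corpus_jsonl <- function(docs, path) {
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    jsonlite::toJSON(as.list(docs[i, c("id", "title", "abstract")]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dplyr::bind_rows(lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble::tibble(id = x$id, title = x$title %||% "",
                   abstract = x$abstract %||% "")
  }))
}

#' Simulate a planted-partition protein interaction graph
#'
#' Nodes are split into equal communities; within-community edges appear
#' with probability `p_in`, between-community edges with `p_out`, and every
#' edge carries a weight uniform in (0, 1]. Community membership is returned
#' as ground truth for embedding-recovery tests.
#'
#' @param n_per_community Nodes per community.
#' @param n_communities Number of communities.
#' @param p_in,p_out Within/between edge probabilities (`p_in > p_out`).
#' @param seed Integer seed.
#'
#' @return List with `edges` (tibble: `from`, `to`, `weight`) and
#'   `membership` (named integer vector, node -> community).
#' @export
sim_ppi <- function(n_per_community, n_communities = 2L,
                    p_in = 0.5, p_out = 0.02, seed = 1L) {
  abort_if(n_per_community < 1 || n_communities < 1, "empty graph")
  abort_if(p_in <= p_out, "`p_in` must exceed `p_out`")
  n <- n_per_community * n_communities
  nodes <- sprintf("P%04d", seq_len(n))
  comm <- rep(seq_len(n_communities), each = n_per_community)
  withr::with_seed(as.integer(seed), {
    pairs <- utils::combn(n, 2L)
    same <- comm[pairs[1, ]] == comm[pairs[2, ]]
    keep <- runif(ncol(pairs)) < ifelse(same, p_in, p_out)
    edges <- tibble::tibble(
      from = nodes[pairs[1, keep]],
      to = nodes[pairs[2, keep]],
      weight = 1 - runif(sum(keep)) # uniform in (0, 1]
    )
    list(edges = edges, membership = setNames(comm, nodes))
  })
}

#' Simulate a case-control cohort with one causal variant
#'
#' Genotypes are drawn at Hardy-Weinberg proportions for the given minor
#' allele frequency; the binary phenotype follows a logistic model with
#' `log(odds_ratio)` per alternate allele, an intercept chosen so the
#' expected case fraction matches `case_fraction` (skewed case-control
#' ratios are the intended regime), and standard-normal covariates with
#' zero true effect.
#'
#' @param n Number of samples.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param odds_ratio Per-allele odds ratio (> 0); 1 gives a null variant.
#' @param case_fraction Expected proportion of cases.
#' @param n_covariates Number of null covariates.
#' @param n_null_variants Additional variants with no phenotype effect.
#' @param seed Integer seed.
#'
#' @return List with tibbles `genotypes` (`sample_id`, `var_causal`,
#'   `var_null_*`), `phenotypes` (`sample_id`, `pheno`), `covariates`
#'   (`sample_id`, `cov_*`) and the true `odds_ratio`.
#' @export
sim_cohort <- function(n, maf = 0.2, odds_ratio = 1, case_fraction = 0.3,
                       n_covariates = 2L, n_null_variants = 0L, seed = 1L) {
  abort_if(maf <= 0 || maf > 0.5, "`maf` must be in (0, 0.5]")
  abort_if(odds_ratio <= 0, "`odds_ratio` must be > 0")
  abort_if(case_fraction <= 0 || case_fraction >= 1,
           "`case_fraction` must be in (0, 1)")
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("S%05d", seq_len(n))
    g <- rbinom(n, 2L, maf)
    beta <- log(odds_ratio)
    b0 <- qlogis(case_fraction) - beta * 2 * maf
    pr <- 1 / (1 + exp(-(b0 + beta * g)))
    y <- rbinom(n, 1L, pr)
    geno <- tibble::tibble(sample_id = ids, var_causal = g)
    for (j in seq_len(n_null_variants)) {
      geno[[sprintf("var_null_%02d", j)]] <- rbinom(n, 2L, maf)
    }
    covs <- tibble::as_tibble(
      c(list(sample_id = ids),
        setNames(replicate(n_covariates, rnorm(n), simplify = FALSE),
                 sprintf("cov_%02d", seq_len(max(n_covariates, 0)))))
    )
    list(
      genotypes = geno,
      phenotypes = tibble::tibble(sample_id = ids, pheno = y),
      covariates = covs,
      odds_ratio = odds_ratio
    )
  })
}
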