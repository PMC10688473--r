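#' Build an adjacency structure from a weighted edge list
#'
#' @param edges Tibble/data frame with columns `from`, `to`, `weight`
#'   (undirected; self-loops rejected, weights must be positive).
#' @return Object of class `ppi_graph` with `nodes` and adjacency lists.
#' @export
ppi_graph <- function(edges) {
  abort_if(nrow(edges) == 0 &&
             !"nodes" %in% names(attributes(edges)), "empty graph")
  abort_if(any(edges$from == edges$to), "self-loops are not allowed")
  abort_if(any(edges$weight <= 0), "edge weights must be positive")
  nodes <- sort(unique(c(edges$from, edges$to)))
  abort_if(length(nodes) == 0, "empty graph")
  idx <- setNames(seq_along(nodes), nodes)
  a <- idx[edges$from]
  b <- idx[edges$to]
  adj <- vector("list", length(nodes))
  wts <- vector("list", length(nodes))
  for (e in seq_along(a)) {
    adj[[a[e]]] <- c(adj[[a[e]]], b[e])
    wts[[a[e]]] <- c(wts[[a[e]]], edges$weight[e])
    adj[[b[e]]] <- c(adj[[b[e]]], a[e])
    wts[[b[e]]] <- c(wts[[b[e]]], edges$weight[e])
  }
  structure(list(nodes = nodes, adj = adj, weights = wts),
            class = "ppi_graph")
}

#' Second-order biased random walks
#'
#' Generates node2vec-style walks: from current node `v` with previous
#' node `t`, the unnormalized probability of stepping to neighbour `x` is
#' `w(v, x)` times `1/p` if `x == t`, `1` if `x` neighbours `t`, and `1/q`
#' otherwise. Each node starts `walks_per_node` walks; isolated nodes
#' yield length-1 walks.
#'
#' @param graph A [ppi_graph()] (or an edge-list tibble, converted
#'   automatically).
#' @param p Return parameter (bias against revisiting the previous node
#'   when > 1).
#' @param q In-out parameter (values > 1 keep the walk local).
#' @param walk_length Maximum number of nodes per walk.
#' @param walks_per_node Walks started at every node.
#' @param seed Integer seed.
#' @return List of character vectors of node names.
#' @export
node2vec_walks <- function(graph, p = 1, q = 1, walk_length = 80L,
                           walks_per_node = 10L, seed = 1L) {
  if (!inherits(graph, "ppi_graph")) graph <- ppi_graph(graph)
  abort_if(walk_length < 1, "`walk_length` must be >= 1")
  n <- length(graph$nodes)
  withr::with_seed(as.integer(seed), {
    walks <- vector("list", n * walks_per_node)
    wi <- 0L
    for (rep_i in seq_len(walks_per_node)) {
      start_order <- sample.int(n)
      for (s in start_order) {
        walk <- integer(walk_length)
        walk[1] <- s
        len <- 1L
        while (len < walk_length) {
          v <- walk[len]
          nbrs <- graph$adj[[v]]
          if (length(nbrs) == 0) break
          w <- graph$weights[[v]]
          if (len == 1L) {
            probs <- w
          } else {
            t_prev <- walk[len - 1L]
            t_nbrs <- graph$adj[[t_prev]]
            bias <- ifelse(nbrs == t_prev, 1 / p,
                           ifelse(nbrs %in% t_nbrs, 1, 1 / q))
            probs <- w * bias
          }
          nxt <- nbrs[sample.int(length(nbrs), 1L, prob = probs)]
          len <- len + 1L
          walk[len] <- nxt
        }
        wi <- wi + 1L
        walks[[wi]] <- graph$nodes[walk[seq_len(len)]]
      }
    }
    walks
  })
}

#' Train a skip-gram embedding over walk corpora
#'
#' Skip-gram with negative sampling (word2vec-style, compiled) over the
#' walk corpus; every node appearing in a walk receives a vector. The
#' default output dimension is 64, the dimensionality used for the protein
#' interaction feature block.
#'
#' @param walks List of node-name vectors from [node2vec_walks()].
#' @param dim Embedding dimension, default 64.
#' @param window Context window half-width.
#' @param negative Negative samples per positive pair.
#' @param epochs Passes over the corpus.
#' @param alpha,alpha_min Initial and final learning rate.
#' @param seed Integer seed (training is reproducible given the seed).
#' @param unit_norm Normalize vectors to unit length (off by default).
#' @return Object of class `ppi_embedding`: matrix `vectors`
#'   (nodes x dim, rownames = node names) plus the training parameters.
#' @export
embed_walks <- function(walks, dim = 64L, window = 10L, negative = 5L,
                        epochs = 5L, alpha = 0.025, alpha_min = 1e-4,
                        seed = 1L, unit_norm = FALSE) {
  abort_if(length(walks) == 0, "no walks supplied")
  vocab <- sort(unique(unlist(walks)))
  abort_if(length(vocab) < 2, "need at least two distinct nodes in walks")
  iwalks <- lapply(walks, function(w) match(w, vocab))
  vec <- sgns_train(iwalks, length(vocab), as.integer(dim),
                    as.integer(window), as.integer(negative),
                    as.integer(epochs), alpha, alpha_min, as.integer(seed))
  rownames(vec) <- vocab
  colnames(vec) <- sprintf("e%d", seq_len(dim))
  if (unit_norm) {
    nrm <- sqrt(rowSums(vec^2))
    vec <- vec / pmax(nrm, 1e-12)
  }
  structure(list(vectors = vec, dim = as.integer(dim), window = window,
                 negative = negative, epochs = epochs, seed = seed),
            class = "ppi_embedding")
}

#' One-call protein interaction network embedding
#'
#' Runs [node2vec_walks()] then [embed_walks()] with the node2vec defaults
#' (p = 1, q = 1, walk length 80, 10 walks per node, window 10, 5 negative
#' samples, 5 epochs, 64 dimensions).
#'
#' @param edges Edge-list tibble (`from`, `to`, `weight`).
#' @param dim,p,q,walk_length,walks_per_node,window,epochs,seed See the
#'   underlying functions.
#' @return Tibble with `protein` and columns `e1`...`e<dim>`.
#' @export
ppi_embedding <- function(edges, dim = 64L, p = 1, q = 1, walk_length = 80L,
                          walks_per_node = 10L, window = 10L, epochs = 5L,
                          seed = 1L) {
  walks <- node2vec_walks(edges, p = p, q = q, walk_length = walk_length,
                          walks_per_node = walks_per_node, seed = seed)
  emb <- embed_walks(walks, dim = dim, window = window, epochs = epochs,
                     seed = seed)
  tibble::as_tibble(emb$vectors, rownames = "protein")
}

#' @method print ppi_embedding
#' @export
print.ppi_embedding <- function(x, ...) {
  cat(sprintf("<ppi_embedding> %d nodes x %d dimensions\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Mean cosine similarity within and between node groups
#'
#' Diagnostic used to check that an embedding separates planted
#' communities: returns the mean pairwise cosine similarity among nodes of
#' the same group and among nodes of different groups.
#'
#' @param embedding A [embed_walks()] result or a plain matrix with
#'   rownames.
#' @param membership Named vector, node -> group.
#' @return Tibble with `intra`, `inter`.
#' @export
community_similarity <- function(embedding, membership) {
  vec <- if (inherits(embedding, "ppi_embedding")) embedding$vectors
  else as.matrix(embedding)
  nodes <- intersect(rownames(vec), names(membership))
  vec <- vec[nodes, , drop = FALSE]
  grp <- membership[nodes]
  nrm <- sqrt(rowSums(vec^2))
  cosim <- (vec %*% t(vec)) / outer(nrm, nrm)
  same <- outer(grp, grp, `==`)
  diag(same) <- NA
  up <- upper.tri(cosim)
  tibble::tibble(
    intra = mean(cosim[up & same], na.rm = TRUE),
    inter = mean(cosim[up & !same], na.rm = TRUE)
  )
}
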