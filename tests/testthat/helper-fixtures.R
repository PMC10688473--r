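# shared fixture builders; everything is generated in code at test time

# small separable three-class dataset
tiny_dataset <- function(seed = 2, n_genes = 60, effect = 2,
                         mix = c(1, 1, 1) / 3) {
  sim_variant_dataset(synthetic_spec(
    seed = seed, n_genes = n_genes, variants_per_gene = 8,
    class_mix = mix, n_informative = 6, effect_size = effect,
    n_noise = 6, missing_rate = 0.05
  ))
}

# random rigid-body motion: rotation (from QR of a random matrix) + shift
random_rigid_motion <- function(seed = 1) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, shift = rnorm(3, sd = 20))
}

apply_rigid_motion <- function(model, motion) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(motion$R), 2, motion$shift, `+`)
  model$atoms$x <- new[, 1]
  model$atoms$y <- new[, 2]
  model$atoms$z <- new[, 3]
  ca <- model$atoms[model$atoms$atom_name == "CA", , drop = FALSE]
  ca <- ca[order(ca$residue_index), , drop = FALSE]
  model$ca <- as.matrix(ca[, c("x", "y", "z")])
  model
}

# build an ideal poly-alanine backbone (N, CA, C per residue) from phi/psi
# by sequential internal-coordinate placement (NeRF)
build_backbone_pdb <- function(n_res, phi, psi, omega = 180) {
  place <- function(a, b, c, bond, angle, torsion) {
    # place atom d with |cd| = bond, angle bcd = angle, torsion abcd = torsion
    ang <- angle * pi / 180
    tor <- torsion * pi / 180
    bc <- c - b
    bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
            bond * sin(ang) * sin(tor))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
  }
  # standard backbone geometry
  bl <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329)
  ba <- c(n_ca_c = 111.0, ca_c_n = 116.2, c_n_ca = 121.7)
  coords <- list()
  # seed the first three atoms
  N1 <- c(0, 0, 0)
  CA1 <- c(bl["n_ca"], 0, 0)
  C1 <- CA1 + c(bl["ca_c"] * cos(pi - ba["n_ca_c"] * pi / 180),
                bl["ca_c"] * sin(pi - ba["n_ca_c"] * pi / 180), 0)
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n_res) {
    prev <- coords[[i - 1]]
    N <- place(prev$N, prev$CA, prev$C, bl["c_n"], ba["ca_c_n"], psi)
    CA <- place(prev$CA, prev$C, N, bl["n_ca"], ba["c_n_ca"], omega)
    C <- place(prev$C, N, CA, bl["ca_c"], ba["n_ca_c"], phi)
    coords[[i]] <- list(N = N, CA = CA, C = C)
  }
  lines <- character(0)
  serial <- 0
  for (i in seq_len(n_res)) {
    for (at in c("N", "CA", "C")) {
      serial <- serial + 1
      el <- substr(at, 1, 1)
      xyz <- coords[[i]][[at]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, at, i, xyz[1], xyz[2], xyz[3], 1.0, 80.0, el))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\nEND\n")
}

# independent brute-force geometry oracles
oracle_contacts <- function(ca, cutoff = 12) {
  n <- nrow(ca)
  vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) {
      i != j && sqrt(sum((ca[i, ] - ca[j, ])^2)) <= cutoff
    }, logical(1)))
  }, numeric(1))
}

oracle_knearest_sum <- function(ca, res_idx, counts, k) {
  n <- nrow(ca)
  vapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j) sqrt(sum((ca[i, ] - ca[j, ])^2)),
                numeric(1))
    ord <- setdiff(order(d, res_idx), i)
    ord <- ord[order(d[ord], res_idx[ord])]
    sum(counts[head(ord, k)])
  }, numeric(1))
}
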