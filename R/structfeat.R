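#' Read a PDB-format predicted structure model
#'
#' Parses fixed-column `ATOM` records (first model only, alternate
#' locations other than `''`/`'A'` skipped) into a per-atom tibble.
#' Per-residue confidence (pLDDT for predicted models) is taken from the
#' CA B-factor. Residues lacking a CA atom are excluded from geometry with
#' a warning. Parsing is delegated to `bio3d::read.pdb()`.
#'
#' @param path Path to a PDB file, or `NULL` when `text` is given.
#' @param text PDB text (as produced by [sim_structure()]).
#' @return Object of class `structure_model`: tibble `atoms` (`residue_index`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z`, `b_factor`),
#'   tibble `residues` (`residue_index`, `residue_name`, `plddt`), and the
#'   CA coordinate matrix `ca` (rows aligned with `residues`).
#' @export
read_structure <- function(path = NULL, text = NULL) {
  abort_if(is.null(path) && is.null(text), "supply `path` or `text`")
  if (is.null(path)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(text, path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("not a parseable PDB file: ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  abort_if(nrow(at) == 0, "no ATOM records present")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elem <- at$elesy
  fix <- is.na(elem) | elem == ""
  elem[fix] <- substr(trimws(at$elety[fix]), 1, 1)
  atoms <- tibble::tibble(
    residue_index = at$resno,
    residue_name = at$resid,
    atom_name = trimws(at$elety),
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z,
    b_factor = at$b
  )
  abort_if(any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))),
           "non-finite coordinates")
  ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  no_ca <- setdiff(unique(atoms$residue_index), ca$residue_index)
  if (length(no_ca) > 0) {
    warning("residue(s) without CA excluded from geometry: ",
            paste(no_ca, collapse = ", "), call. = FALSE)
  }
  ca <- ca[order(ca$residue_index), , drop = FALSE]
  residues <- tibble::tibble(
    residue_index = ca$residue_index,
    residue_name = ca$residue_name,
    plddt = ca$b_factor
  )
  structure(
    list(atoms = atoms, residues = residues,
         ca = as.matrix(ca[, c("x", "y", "z")])),
    class = "structure_model"
  )
}

#' @method print structure_model
#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues, %d atoms\n",
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

ca_dist_matrix <- function(model) {
  as.matrix(stats::dist(model$ca))
}

#' Residue contact counts
#'
#' For every residue, the number of other residues whose alpha-carbon lies
#' within `cutoff` Angstroms (inclusive) of this residue's alpha-carbon.
#' The residue itself is excluded; immediate sequence neighbours count.
#'
#' @param model A [read_structure()] model.
#' @param cutoff Contact distance in Angstroms, default 12.
#' @return Tibble `residue_index`, `contacts`.
#' @export
residue_contacts <- function(model, cutoff = 12.0) {
  abort_if(nrow(model$residues) < 1, "model has no residues")
  D <- ca_dist_matrix(model)
  counts <- rowSums(D <= cutoff) - 1L
  tibble::tibble(residue_index = model$residues$residue_index,
                 contacts = as.integer(counts))
}

# standard atomic masses for centre-of-mass computation
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971)

#' Distance from each residue's alpha-carbon to the protein centre of mass
#'
#' The centre of mass is the atomic-mass-weighted mean over all atoms
#' (standard element masses; unknown elements fall back to 12.0 with a
#' warning).
#'
#' @param model A [read_structure()] model.
#' @return Tibble `residue_index`, `com_distance` (Angstroms).
#' @export
com_distance <- function(model) {
  abort_if(nrow(model$atoms) < 1, "model has no atoms")
  mass <- ELEMENT_MASS[model$atoms$element]
  if (anyNA(mass)) {
    warning("unknown element(s) assigned mass 12.0: ",
            paste(unique(model$atoms$element[is.na(mass)]), collapse = ", "),
            call. = FALSE)
    mass[is.na(mass)] <- 12.0
  }
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  com <- colSums(xyz * mass) / sum(mass)
  d <- sqrt(rowSums(sweep(model$ca, 2, com)^2))
  tibble::tibble(residue_index = model$residues$residue_index,
                 com_distance = d)
}

#' Variant counts over each residue's 3D neighbourhood
#'
#' For every residue, finds its `k` spatially nearest other residues by
#' alpha-carbon distance (self excluded; ties broken in favour of the lower
#' residue index) and sums the pathogenic and population variant counts
#' mapped onto those residues. Residues with no mapped variants contribute
#' zero; when the chain has `k` or fewer other residues, all of them are
#' used.
#'
#' @param model A [read_structure()] model.
#' @param variant_map Tibble `residue_index`, `n_pathogenic`,
#'   `n_population` (absent residues count 0; counts must be >= 0).
#' @param k Neighbourhood size, default 9.
#' @return Tibble `residue_index`, `n_proximal_pathogenic`,
#'   `n_proximal_population`.
#' @export
proximal_variant_counts <- function(model, variant_map, k = 9L) {
  res_idx <- model$residues$residue_index
  n <- length(res_idx)
  path_counts <- pop_counts <- setNames(numeric(n), res_idx)
  if (!is.null(variant_map) && nrow(variant_map) > 0) {
    abort_if(any(variant_map$n_pathogenic < 0 | variant_map$n_population < 0),
             "variant counts must be >= 0")
    m <- match(as.character(variant_map$residue_index), names(path_counts))
    ok <- !is.na(m)
    path_counts[m[ok]] <- variant_map$n_pathogenic[ok]
    pop_counts[m[ok]] <- variant_map$n_population[ok]
  }
  D <- ca_dist_matrix(model)
  out_path <- out_pop <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # order by distance, ties by lower residue index
    ord <- others[order(D[i, others], res_idx[others])]
    nb <- head(ord, k)
    out_path[i] <- sum(path_counts[nb])
    out_pop[i] <- sum(pop_counts[nb])
  }
  tibble::tibble(residue_index = res_idx,
                 n_proximal_pathogenic = out_path,
                 n_proximal_population = out_pop)
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# deterministic quasi-uniform sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area and relative solvent accessibility
#'
#' Shrake-Rupley SASA: each atom is surrounded by a deterministic spiral of
#' `n_sphere_points` test points at radius `vdW + probe`; points not inside
#' any neighbouring atom's probe-expanded sphere are accessible. Atomic
#' SASA is summed per residue and divided by the residue's theoretical
#' maximum accessible surface area (Tien et al. 2013 values) to give RSA;
#' residues with RSA strictly below 0.20 are classed `buried`, all others
#' `exposed`.
#'
#' @param model A [read_structure()] model.
#' @param probe_radius Probe radius in Angstroms (water: 1.4).
#' @param n_sphere_points Test points per atom, default 960.
#' @return Tibble `residue_index`, `sasa`, `rsa`, `burial`.
#' @export
residue_rsa <- function(model, probe_radius = 1.4, n_sphere_points = 960L) {
  atoms <- model$atoms
  abort_if(nrow(atoms) < 1, "model has no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- VDW_RADII[atoms$element]
  radii[is.na(radii)] <- 1.70
  r_ext <- radii + probe_radius
  pts <- sphere_points(n_sphere_points)
  n_at <- nrow(xyz)
  sasa <- numeric(n_at)
  # pairwise distances once; only spheres that can overlap matter
  Dat <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n_at)) {
    nb <- which(Dat[i, ] < r_ext[i] + r_ext & seq_len(n_at) != i)
    test <- sweep(pts * r_ext[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_sphere_points
    } else {
      occluded <- rep(FALSE, n_sphere_points)
      for (j in nb) {
        d2 <- rowSums(sweep(test, 2, xyz[j, ])^2)
        occluded <- occluded | d2 < r_ext[j]^2
        if (all(occluded)) break
      }
      acc <- sum(!occluded)
    }
    sasa[i] <- 4 * pi * r_ext[i]^2 * acc / n_sphere_points
  }
  res_sasa <- tapply(sasa, atoms$residue_index, sum)
  res_idx <- model$residues$residue_index
  total <- as.numeric(res_sasa[as.character(res_idx)])
  total[is.na(total)] <- 0
  max_asa <- MAX_ASA_TIEN[model$residues$residue_name]
  max_asa[is.na(max_asa)] <- mean(MAX_ASA_TIEN)
  rsa <- total / max_asa
  tibble::tibble(
    residue_index = res_idx, sasa = total, rsa = rsa,
    burial = ifelse(rsa < 0.20, "buried", "exposed")
  )
}

# theoretical maximum ASA per residue (Tien et al. 2013, theoretical set)
MAX_ASA_TIEN <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# torsion angle (degrees) for four points
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- n1 / sqrt(sum(n1^2))
  m2 <- n2 / sqrt(sum(n2^2))
  b2u <- b2 / sqrt(sum(b2^2))
  # IUPAC sign: torsion = atan2((n1 x n2) . b2_unit, n1 . n2)
  x <- sum(m1 * m2)
  cr <- c(m1[2] * m2[3] - m1[3] * m2[2],
          m1[3] * m2[1] - m1[1] * m2[3],
          m1[1] * m2[2] - m1[2] * m2[1])
  y <- sum(cr * b2u)
  atan2(y, x) * 180 / pi
}

ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Three-state secondary structure from backbone dihedrals
#'
#' Assigns H (helix) to runs of at least four consecutive residues whose
#' (phi, psi) both lie within 40 degrees of (-60, -45), E (strand) to runs
#' of at least two residues within 45 degrees of (-120, 130), and C (coil)
#' otherwise. Residues lacking backbone N/CA/C atoms — including chain
#' termini, where phi or psi is undefined — are C.
#'
#' @param model A [read_structure()] model.
#' @return Tibble `residue_index`, `secondary`.
#' @export
secondary_structure <- function(model) {
  res_idx <- model$residues$residue_index
  n <- length(res_idx)
  ss <- rep("C", n)
  if (n >= 3) {
    bb <- lapply(res_idx, function(ri) {
      a <- model$atoms[model$atoms$residue_index == ri, , drop = FALSE]
      get_at <- function(nm) {
        row <- a[a$atom_name == nm, , drop = FALSE]
        if (nrow(row) == 0) return(NULL)
        as.numeric(row[1, c("x", "y", "z")])
      }
      list(N = get_at("N"), CA = get_at("CA"), C = get_at("C"))
    })
    phi <- psi <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ok <- !is.null(bb[[i]]$N) && !is.null(bb[[i]]$CA) && !is.null(bb[[i]]$C)
      if (!ok) next
      if (i > 1 && !is.null(bb[[i - 1]]$C)) {
        phi[i] <- dihedral(bb[[i - 1]]$C, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
      }
      if (i < n && !is.null(bb[[i + 1]]$N)) {
        psi[i] <- dihedral(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, bb[[i + 1]]$N)
      }
    }
    helix_like <- !is.na(phi) & !is.na(psi) &
      ang_diff(phi, -60) <= 40 & ang_diff(psi, -45) <= 40
    strand_like <- !is.na(phi) & !is.na(psi) &
      ang_diff(phi, -120) <= 45 & ang_diff(psi, 130) <= 45
    assign_runs <- function(flag, min_len, code) {
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        if (r$values[j] && r$lengths[j] >= min_len) {
          ss[starts[j]:ends[j]] <<- code
        }
      }
    }
    assign_runs(strand_like, 2L, "E")
    assign_runs(helix_like, 4L, "H") # helix wins where both would apply
  }
  tibble::tibble(residue_index = res_idx, secondary = ss)
}

#' All residue-level structural features in one table
#'
#' Convenience wrapper combining contacts, centre-of-mass distance, SASA /
#' RSA / burial, secondary structure, proximal variant counts and pLDDT.
#' Low-confidence residues are deliberately not excluded: the confidence
#' score itself is an informative feature.
#'
#' @param model A [read_structure()] model.
#' @param variant_map Optional tibble for [proximal_variant_counts()].
#' @param contact_cutoff,k,probe_radius,n_sphere_points Parameters of the
#'   individual feature functions.
#' @return Tibble with one row per residue.
#' @export
structure_features <- function(model, variant_map = NULL,
                               contact_cutoff = 12.0, k = 9L,
                               probe_radius = 1.4, n_sphere_points = 960L) {
  out <- residue_contacts(model, contact_cutoff) |>
    dplyr::left_join(com_distance(model), by = "residue_index") |>
    dplyr::left_join(residue_rsa(model, probe_radius, n_sphere_points),
                     by = "residue_index") |>
    dplyr::left_join(secondary_structure(model), by = "residue_index") |>
    dplyr::left_join(
      proximal_variant_counts(
        model,
        variant_map %||% tibble::tibble(residue_index = integer(),
                                        n_pathogenic = numeric(),
                                        n_population = numeric()),
        k),
      by = "residue_index")
  dplyr::left_join(out, model$residues[, c("residue_index", "plddt")],
                   by = "residue_index")
}
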