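test_that("contact counts match forced geometry and the brute-force oracle", {
  # collinear CAs at x = 0, 10, 20: middle residue touches both ends
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 90.00           C",
    "ATOM      2  CA  ALA A   2      10.000   0.000   0.000  1.00 90.00           C",
    "ATOM      3  CA  ALA A   3      20.000   0.000   0.000  1.00 90.00           C",
    "END", sep = "\n")
  m <- read_structure(text = txt)
  expect_equal(residue_contacts(m, 12)$contacts, c(1L, 2L, 1L))

  m50 <- read_structure(text = sim_structure(50, seed = 13))
  expect_equal(residue_contacts(m50, 12)$contacts,
               as.integer(oracle_contacts(m50$ca, 12)))
})

test_that("centre-of-mass distances match the mass-weighted formula", {
  # two equal-mass atoms at (0,0,0) and (2,0,0); CA at the origin
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 50.00           C",
    "ATOM      2  CB  ALA A   1       2.000   0.000   0.000  1.00 50.00           C",
    "END", sep = "\n")
  m <- read_structure(text = txt)
  expect_equal(com_distance(m)$com_distance, 1.0, tolerance = 1e-9)

  m50 <- read_structure(text = sim_structure(50, seed = 17))
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  w <- masses[m50$atoms$element]
  xyz <- as.matrix(m50$atoms[, c("x", "y", "z")])
  com <- colSums(xyz * w) / sum(w)
  want <- sqrt(rowSums(sweep(m50$ca, 2, com)^2))
  expect_equal(com_distance(m50)$com_distance, want, tolerance = 1e-9)
})

test_that("proximal variant sums equal the k-nearest brute-force oracle", {
  m <- read_structure(text = sim_structure(50, seed = 19))
  set.seed(19)
  vm <- tibble::tibble(
    residue_index = sample(m$residues$residue_index, 30),
    n_pathogenic = rpois(30, 2),
    n_population = rpois(30, 1)
  )
  got <- proximal_variant_counts(m, vm, k = 9)
  counts_p <- setNames(rep(0, 50), m$residues$residue_index)
  counts_g <- counts_p
  counts_p[as.character(vm$residue_index)] <- vm$n_pathogenic
  counts_g[as.character(vm$residue_index)] <- vm$n_population
  expect_equal(got$n_proximal_pathogenic,
               oracle_knearest_sum(m$ca, m$residues$residue_index,
                                   counts_p, 9))
  expect_equal(got$n_proximal_population,
               oracle_knearest_sum(m$ca, m$residues$residue_index,
                                   counts_g, 9))

  # k exceeding n - 1 sums over all other residues
  m5 <- read_structure(text = sim_structure(5, seed = 2))
  vm5 <- tibble::tibble(residue_index = 1:5, n_pathogenic = 1,
                        n_population = 2)
  got5 <- proximal_variant_counts(m5, vm5, k = 9)
  expect_equal(got5$n_proximal_pathogenic, rep(4, 5))
  # an all-zero map gives zeros
  expect_equal(
    proximal_variant_counts(m5, NULL, k = 9)$n_proximal_pathogenic,
    rep(0, 5))
})

test_that("isolated sphere SASA matches the analytic value", {
  txt <- paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 50.00           C",
    "END", sep = "\n")
  m <- read_structure(text = txt)
  out <- residue_rsa(m, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(out$sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
})

test_that("burial boundary is strict at RSA 0.20", {
  expect_equal(categorize(c(0.19, 0.20), rule_rsa()),
               c("buried", "exposed"))
})

test_that("terminal residues are at least as exposed as the core on a globule", {
  m <- read_structure(text = sim_structure(40, seed = 23, compact = TRUE))
  out <- residue_rsa(m, n_sphere_points = 240)
  core <- out$rsa[15:25]
  expect_gte(out$rsa[1], min(core))
  expect_gte(out$rsa[40], min(core))
  # denser sampling changes the estimate only slightly
  fine <- residue_rsa(m, n_sphere_points = 2400)
  expect_lt(max(abs(fine$rsa - out$rsa)), 0.05)
})

test_that("all geometry features are rigid-motion invariant", {
  m <- read_structure(text = sim_structure(40, seed = 29))
  moved <- apply_rigid_motion(m, random_rigid_motion(5))
  expect_equal(residue_contacts(moved)$contacts,
               residue_contacts(m)$contacts)
  expect_equal(com_distance(moved)$com_distance,
               com_distance(m)$com_distance, tolerance = 1e-6)
  vm <- tibble::tibble(residue_index = 1:40,
                       n_pathogenic = rpois(40, 1), n_population = 0)
  expect_equal(proximal_variant_counts(moved, vm)$n_proximal_pathogenic,
               proximal_variant_counts(m, vm)$n_proximal_pathogenic)
  expect_equal(residue_rsa(moved, n_sphere_points = 240)$rsa,
               residue_rsa(m, n_sphere_points = 240)$rsa, tolerance = 0.02)
})

test_that("secondary structure recovers ideal helix and extended dihedrals", {
  helix <- read_structure(text = build_backbone_pdb(12, phi = -60, psi = -45))
  ss_h <- secondary_structure(helix)$secondary
  # interior residues are helical; termini lack a dihedral and stay coil
  expect_true(all(ss_h[2:11] == "H"))
  expect_equal(ss_h[c(1, 12)], c("C", "C"))

  ext <- read_structure(text = build_backbone_pdb(10, phi = -120, psi = 130))
  ss_e <- secondary_structure(ext)$secondary
  expect_true(all(ss_e %in% c("E", "C")))
  expect_true(any(ss_e == "E"))

  # structures without backbone N/C atoms (CA traces) are all coil
  trace <- read_structure(text = sim_structure(10, seed = 3))
  expect_true(all(secondary_structure(trace)$secondary == "C"))
  # fewer than 3 residues: all coil
  two <- read_structure(text = build_backbone_pdb(2, -60, -45))
  expect_true(all(secondary_structure(two)$secondary == "C"))
})

test_that("low-confidence residues are kept and pLDDT is carried through", {
  pdb <- sim_structure(15, seed = 31)
  m <- read_structure(text = pdb)
  feats <- structure_features(m, n_sphere_points = 120)
  expect_equal(nrow(feats), 15) # nothing dropped whatever the confidence
  expect_true(any(feats$plddt < 50)) # low-confidence residues present
  expect_false(anyNA(feats$contacts))
})

test_that("parser rejects empty input and reports missing CA residues", {
  expect_error(read_structure(text = "END\n"), "")
  no_ca <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 50.00           C",
    "ATOM      2  CB  ALA A   2       3.000   0.000   0.000  1.00 50.00           C",
    "END", sep = "\n")
  expect_warning(m <- read_structure(text = no_ca), "without CA")
  expect_equal(nrow(m$residues), 1)
})
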