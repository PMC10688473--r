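test_that("neutral sampling follows the min-2 / lower-class-count rule", {
  pool <- tibble::tibble(gene = rep(c("G1", "G2", "G3"), each = 20),
                         variant_id = paste0("n", 1:60))
  counts <- tibble::tibble(gene = c("G1", "G2"),
                           n_gof = c(10, 0), n_lof = c(4, 1))
  set.seed(1)
  out <- sample_neutral(counts, pool)
  expect_equal(sum(out$gene == "G1"), 4)   # min(10, 4)
  expect_equal(sum(out$gene == "G2"), 2)   # minimum of two applies
  expect_true(all(out$label == "NEUTRAL"))
  expect_false(anyDuplicated(out$variant_id) > 0) # without replacement

  # capped by pool availability
  small_pool <- pool[pool$gene == "G1", ][1:3, ]
  out2 <- sample_neutral(tibble::tibble(gene = "G1", n_gof = 5, n_lof = 5),
                         small_pool)
  expect_equal(nrow(out2), 3)

  # empty pool skips the gene with a warning
  expect_warning(
    out3 <- sample_neutral(tibble::tibble(gene = "GX", n_gof = 3, n_lof = 3),
                           pool),
    "skipped"
  )
  expect_equal(nrow(out3), 0)
})

test_that("gene-disjoint splitter hits the target share with stratification", {
  sim <- sim_variant_dataset(synthetic_spec(
    seed = 3, n_genes = 300, variants_per_gene = 10,
    class_mix = c(.05, .475, .475)))
  set.seed(42)
  sp <- split_by_gene(sim$variants, train_fraction = 0.9, restarts = 200)
  expect_gte(sp$train_share, 0.88)
  expect_lte(sp$train_share, 0.92)
  # hard constraint: no gene on both sides
  expect_length(intersect(unique(sp$train$gene), unique(sp$test$gene)), 0)
  # per-class stratification within 3 percentage points
  for (cl in unique(sim$variants$label)) {
    share <- sum(sp$train$label == cl) / sum(sim$variants$label == cl)
    expect_lt(abs(share - 0.9), 0.03)
  }
})

test_that("splitter handles the single-gene degenerate case", {
  v <- tibble::tibble(gene = "G1", label = rep(c("GOF", "LOF"), 5))
  set.seed(1)
  sp <- split_by_gene(v, 0.9, restarts = 10)
  expect_true(nrow(sp$train) == 10 || nrow(sp$test) == 10)
})

test_that("homology clustering joins identical and separates random sequences", {
  set.seed(7)
  rand_seq <- function(n) paste(sample(names(Biostrings::AMINO_ACID_CODE)[1:20],
                                       n, replace = TRUE), collapse = "")
  s1 <- rand_seq(200)
  s2 <- rand_seq(200)
  # identical sequences cluster together
  cl <- cluster_homologs(c(a = s1, b = s1))
  expect_equal(length(unique(cl$members$cluster)), 1)
  # two random length-200 sequences: verify with the exact-alignment oracle
  pid <- alignment_identity(s1, s2)
  expect_lt(pid, 0.4)
  cl2 <- cluster_homologs(c(a = s1, b = s2))
  expect_equal(length(unique(cl2$members$cluster)), 2)
  # threshold 1 puts every distinct sequence in its own cluster
  s3 <- sub("^.", "W", s1)
  cl3 <- cluster_homologs(c(a = s1, b = s3), identity_threshold = 1)
  expect_equal(length(unique(cl3$members$cluster)), 2)
  expect_error(cluster_homologs(character(0)), "no sequences")
})

test_that("homology filter keeps the best-represented cluster member", {
  train <- tibble::tibble(gene = c("gA", "gA", "gA", "gA", "gA"),
                          protein = "A", label = "LOF")
  test <- tibble::tibble(gene = c("gB", "gB"), protein = "B", label = "LOF")
  sp <- structure(list(train = train, test = test,
                       gene_assignment = c(gA = "train", gB = "test"),
                       score = 0, train_share = 5 / 7),
                  class = "split_result")
  clustering <- structure(list(
    members = tibble::tibble(protein = c("A", "B"), cluster = c(1L, 1L),
                             representative = "A"),
    representatives = "A"), class = "homology_clustering")
  out <- apply_homology_filter(sp, clustering)
  # A has 5 labeled variants vs B's 2: B's variants are dropped
  expect_equal(nrow(out$train), 5)
  expect_equal(nrow(out$test), 0)

  # disjoint clusters leave the split unchanged
  clustering2 <- structure(list(
    members = tibble::tibble(protein = c("A", "B"), cluster = c(1L, 2L),
                             representative = c("A", "B")),
    representatives = c("A", "B")), class = "homology_clustering")
  out2 <- apply_homology_filter(sp, clustering2)
  expect_equal(nrow(out2$train), 5)
  expect_equal(nrow(out2$test), 2)

  # all proteins in one cluster: a single protein survives overall
  big <- structure(list(train = train,
                        test = dplyr::mutate(test, protein = "C"),
                        gene_assignment = c(gA = "train", gB = "test"),
                        score = 0, train_share = 5 / 7),
                   class = "split_result")
  clustering3 <- structure(list(
    members = tibble::tibble(protein = c("A", "C"), cluster = 1L,
                             representative = "A"),
    representatives = "A"), class = "homology_clustering")
  out3 <- apply_homology_filter(big, clustering3)
  expect_equal(unique(c(out3$train$protein, out3$test$protein)), "A")
})
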