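test_that("ensemble respects its configuration and votes softly", {
  sim <- tiny_dataset(seed = 5)
  pre <- fit_preprocessor(dplyr::select(sim$features, -variant_id))
  mat <- transform_features(sim$features, pre)
  labels <- sim$variants$label
  cfg <- default_config(ensemble_size = 3L, n_estimators = 40L)
  mdl <- train_ensemble(mat, labels, cfg, seed = 1)
  expect_equal(mdl$n_members, 3)
  expect_equal(default_config()$ensemble_size, 27) # final architecture
  expect_error(train_ensemble(mat, labels,
                              default_config(ensemble_size = 100L)),
               "between 1 and 64")

  prob <- predict(mdl, mat)
  expect_equal(max(abs(rowSums(as.matrix(prob)) - 1)), 0, tolerance = 1e-9)

  # single-member ensemble returns that member's probabilities unchanged
  one <- train_ensemble(mat, labels, default_config(ensemble_size = 1L,
                                                    n_estimators = 40L),
                        seed = 1)
  p_member <- predict(one$members[[1]], xgboost::xgb.DMatrix(mat))
  expect_equal(as.matrix(predict(one, mat)), unname(p_member),
               tolerance = 1e-7, ignore_attr = TRUE)

  # members with different seeds differ in at least one prediction
  m1 <- predict(mdl$members[[1]], xgboost::xgb.DMatrix(mat))
  m2 <- predict(mdl$members[[2]], xgboost::xgb.DMatrix(mat))
  expect_false(isTRUE(all.equal(m1, m2)))

  # permuting member order leaves the vote unchanged
  mdl_perm <- mdl
  mdl_perm$members <- rev(mdl$members)
  expect_equal(as.matrix(predict(mdl_perm, mat)),
               as.matrix(predict(mdl, mat)), tolerance = 1e-12)

  # column mismatch errors name the expected columns
  bad <- mat[, rev(colnames(mat))]
  expect_error(predict(mdl, bad), "training order")
})

test_that("attributions are additive and rank planted informative features", {
  hits <- 0L
  for (seed in 1:10) {
    sim <- tiny_dataset(seed = seed, n_genes = 40)
    pre <- fit_preprocessor(dplyr::select(sim$features, -variant_id))
    mat <- transform_features(sim$features, pre)
    mdl <- train_ensemble(mat, sim$variants$label,
                          default_config(ensemble_size = 3L,
                                         n_estimators = 60L), seed = seed)
    att <- attribute_ensemble(mdl, mat[1:60, ])
    if (seed == 1) {
      # additivity: per-member contributions + bias reproduce the margin
      m1 <- mdl$members[[1]]
      dm <- xgboost::xgb.DMatrix(mat[1:10, ])
      margin <- predict(m1, dm, outputmargin = TRUE)
      ctr <- predict(m1, dm, predcontrib = TRUE)
      expect_equal(apply(ctr, c(1, 2), sum), unname(margin),
                   tolerance = 1e-4, ignore_attr = TRUE)
      # a feature never split on gets zero attribution: constant columns
      # are dropped by the preprocessor, so check a noise feature is weak
      expect_true(all(c(sim$informative, paste0("noise_0", 1:6)) %in%
                        unique(att$mean_abs$feature)))
    }
    rank_tbl <- att$mean_abs |>
      dplyr::group_by(feature) |>
      dplyr::summarise(score = mean(mean_abs_attribution)) |>
      dplyr::arrange(dplyr::desc(score))
    top <- head(rank_tbl$feature, length(sim$informative))
    if (all(top %in% sim$informative)) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})

test_that("nested CV separates separable data and is honest on null data", {
  sim <- tiny_dataset(seed = 11, n_genes = 50, effect = 2)
  space <- search_space(n_estimators = c(40L, 80L),
                        ensemble_size = c(5L, 7L))
  cv <- nested_cv(as.data.frame(dplyr::select(sim$features, -variant_id)),
                  sim$variants$label, sim$variants$gene, space = space,
                  n_outer = 5L, n_inner = 3L, n_trials = 2L, seed = 2)
  expect_equal(nrow(cv$outer_scores), 5)
  expect_gt(median(cv$outer_scores$macro_f1), 0.8)
  # every config drawn respects the ensemble-size bounds
  sizes <- vapply(cv$configs, `[[`, numeric(1), "ensemble_size")
  expect_true(all(sizes >= 5 & sizes <= 7))

  # a zero-effect dataset can only reach chance-level macro-F1;
  # a large gap would indicate leakage through preprocessing/oversampling
  null_sim <- tiny_dataset(seed = 12, n_genes = 50, effect = 0)
  cv0 <- nested_cv(as.data.frame(dplyr::select(null_sim$features,
                                               -variant_id)),
                   null_sim$variants$label, null_sim$variants$gene,
                   space = space, n_outer = 3L, n_inner = 3L,
                   n_trials = 2L, seed = 3)
  expect_lt(median(cv0$outer_scores$macro_f1), 0.45)
})

test_that("nested CV folds are gene-grouped", {
  sim <- tiny_dataset(seed = 13, n_genes = 30)
  set.seed(1)
  folds <- gainloss:::gene_folds(sim$variants$gene, sim$variants$label, 3)
  per_gene <- tapply(folds, sim$variants$gene,
                     function(f) length(unique(f)))
  expect_true(all(per_gene == 1))
})

test_that("model directory serialization round-trips predictions", {
  sim <- tiny_dataset(seed = 6, n_genes = 20)
  pre <- fit_preprocessor(dplyr::select(sim$features, -variant_id))
  mat <- transform_features(sim$features, pre)
  mdl <- train_ensemble(mat, sim$variants$label,
                        default_config(ensemble_size = 2L,
                                       n_estimators = 30L),
                        seed = 4, preprocessor = pre)
  dir <- tempfile("ens")
  write_ensemble(mdl, dir)
  back <- read_ensemble(dir)
  expect_equal(as.matrix(predict(back, mat)),
               as.matrix(predict(mdl, mat)), tolerance = 1e-7)
  # raw tables go through the stored preprocessor
  expect_equal(as.matrix(predict(back, sim$features)),
               as.matrix(predict(mdl, mat)), tolerance = 1e-7)
  unlink(dir, recursive = TRUE)
})
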