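# independent oracle: maximize the Jeffreys-penalized log-likelihood by
# general-purpose optimization
oracle_firth <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * w, X)
    -(sum(y * eta - log1p(exp(eta))) +
        0.5 * determinant(info, logarithm = TRUE)$modulus)
  }
  optim(rep(0, ncol(X)), nll, method = "BFGS")$par
}

test_that("Firth estimates stay finite under complete separation", {
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 0, 1, 1, 1) # perfectly separated: the MLE diverges
  fit <- firth_fit(cbind(1, x), y)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients$estimate)))
  expect_lt(abs(fit$coefficients$estimate[2]), 10)
  # random separable datasets remain finite too
  set.seed(30)
  for (i in 1:10) {
    xx <- rnorm(40)
    yy <- as.integer(xx > 0)
    f <- firth_fit(cbind(1, xx), yy)
    expect_true(all(is.finite(f$coefficients$estimate)))
  }
})

test_that("2x2 Firth slope equals the +0.5-cell log odds ratio and the oracle", {
  tab <- c(a = 12, b = 5, c = 4, d = 9) # exposed cases/controls etc.
  x <- c(rep(1, tab["a"] + tab["b"]), rep(0, tab["c"] + tab["d"]))
  y <- c(rep(1, tab["a"]), rep(0, tab["b"]),
         rep(1, tab["c"]), rep(0, tab["d"]))
  X <- cbind(1, x)
  fit <- firth_fit(X, y)
  closed <- log((tab["a"] + .5) * (tab["d"] + .5) /
                  ((tab["b"] + .5) * (tab["c"] + .5)))
  expect_equal(unname(fit$coefficients$estimate[2]), unname(closed),
               tolerance = 1e-5)
  expect_equal(unname(fit$coefficients$estimate), oracle_firth(X, y),
               tolerance = 1e-4)
})

test_that("Firth slope is near zero on balanced null data", {
  set.seed(31)
  ch <- sim_cohort(4000, maf = 0.3, odds_ratio = 1, case_fraction = 0.5,
                   seed = 31)
  fit <- firth_fit(cbind(1, ch$genotypes$var_causal), ch$phenotypes$pheno)
  expect_lt(abs(fit$coefficients$estimate[2]), 0.15)
})

test_that("Firth recovers a planted odds ratio within its confidence interval", {
  ch <- sim_cohort(5000, maf = 0.2, odds_ratio = 5, case_fraction = 0.2,
                   seed = 32)
  fit <- firth_fit(cbind(1, ch$genotypes$var_causal), ch$phenotypes$pheno)
  co <- fit$coefficients[2, ]
  lo <- co$estimate - 1.96 * co$std_error
  hi <- co$estimate + 1.96 * co$std_error
  expect_gt(log(5), lo)
  expect_lt(log(5), hi)
})

test_that("type-I error is near nominal on null simulations", {
  rejections <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    ch <- sim_cohort(2000, maf = 0.25, odds_ratio = 1, case_fraction = 0.3,
                     seed = 1000 + i)
    fit <- firth_fit(cbind(1, ch$genotypes$var_causal),
                     ch$phenotypes$pheno)
    if (fit$coefficients$p_value[2] < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # 4 SD Monte-Carlo band around 0.05
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("penalized LRT agrees in order of magnitude with Wald", {
  ch <- sim_cohort(2000, maf = 0.2, odds_ratio = 3, case_fraction = 0.3,
                   seed = 33)
  fit <- firth_fit(cbind(intercept = 1, genotype = ch$genotypes$var_causal),
                   ch$phenotypes$pheno)
  lrt <- firth_lrt(fit, "genotype")
  expect_lt(lrt$p_value, 1e-6)
  expect_lt(fit$coefficients$p_value[2], 1e-6)
})

test_that("the PheWAS scan applies case, MAC and Bonferroni rules", {
  expect_equal(bonferroni_threshold(0.05, 1075), 0.05 / 1075)
  ch <- sim_cohort(1500, maf = 0.2, odds_ratio = 4, case_fraction = 0.25,
                   n_covariates = 2, n_null_variants = 2, seed = 40)
  # a second phenotype with too few cases must be skipped
  phe <- ch$phenotypes
  phe$rare_pheno <- c(rep(1L, 10), rep(0L, nrow(phe) - 10))
  res <- run_phewas(ch$genotypes, phe, ch$covariates,
                    min_cases = 50, min_mac = 20)
  expect_equal(res$n_phenotypes_tested, 1)
  expect_equal(res$threshold, 0.05)
  td <- tidy(res)
  expect_true(td$significant[td$variant == "var_causal"])
  expect_false(any(td$significant[grepl("null", td$variant)]))

  # replication-style thresholds admit rarer phenotypes
  res2 <- run_phewas(ch$genotypes, phe, ch$covariates,
                     min_cases = 5, min_mac = 10)
  expect_equal(res2$n_phenotypes_tested, 2)
  expect_equal(res2$threshold, 0.025)

  # misaligned sample ids error out
  bad <- ch$phenotypes
  bad$sample_id[1] <- "SOMEONE_ELSE"
  expect_error(run_phewas(ch$genotypes, bad, NULL), "misaligned")
})

test_that("planted associations separate from null variants across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    ch <- sim_cohort(2000, maf = 0.15, odds_ratio = 5, case_fraction = 0.2,
                     n_covariates = 0, n_null_variants = 3, seed = seed)
    res <- run_phewas(ch$genotypes, ch$phenotypes, NULL,
                      min_cases = 50, min_mac = 20)
    td <- tidy(res)
    causal_sig <- td$significant[td$variant == "var_causal"]
    null_sig <- td$significant[grepl("null", td$variant)]
    if (causal_sig && !any(null_sig)) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("MAC is computed on analyzed samples only", {
  ch <- sim_cohort(500, maf = 0.1, odds_ratio = 1, case_fraction = 0.4,
                   seed = 50)
  g <- ch$genotypes
  g$var_causal[1:100] <- NA # masked genotypes leave the analysis
  res <- run_phewas(g, ch$phenotypes, NULL, min_cases = 50, min_mac = 1)
  mac_expected <- min(sum(g$var_causal[-(1:100)]),
                      sum(2 - g$var_causal[-(1:100)]))
  expect_equal(res$results$mac[1], mac_expected)
})
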