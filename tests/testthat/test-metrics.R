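test_that("precision/recall/F1 follow the set definitions", {
  # identical sets
  expect_equal(unname(precision_recall_f1(c("a", "b"), c("a", "b"))),
               c(1, 1, 1))
  # disjoint sets
  expect_equal(unname(precision_recall_f1(c("a", "a"), c("b", "b"),
                                          positive = "a")), c(0, 0, 0))
  # |y| = 4, |y'| = 5, |intersection| = 3
  y_true <- c(rep("P", 5), rep("N", 5))
  y_pred <- c(rep("P", 3), rep("N", 6), "P")
  got <- precision_recall_f1(y_pred, y_true, positive = "P")
  expect_equal(unname(got),
               c(3 / 4, 3 / 5, 2 * (0.75 * 0.6) / (0.75 + 0.6)))
})

test_that("macro-F1 averages per-class F1 unweighted", {
  expect_equal(macro_f1(c("a", "b"), c("a", "b")), 1)
  # one class perfect, the other never predicted
  y_true <- c("a", "a", "b")
  y_pred <- c("a", "a", "a")
  f_a <- precision_recall_f1(y_pred, y_true, positive = "a")[["f1"]]
  f_b <- precision_recall_f1(y_pred, y_true, positive = "b")[["f1"]]
  expect_equal(macro_f1(y_pred, y_true, classes = c("a", "b")),
               mean(c(f_a, f_b)))
  # invariant under class relabeling
  relab <- c(a = "z", b = "y")
  expect_equal(macro_f1(relab[y_pred], relab[y_true]),
               macro_f1(y_pred, y_true))
  # the support-weighted variant differs when supports differ
  expect_equal(macro_f1(y_pred, y_true, classes = c("a", "b"),
                        weighted = TRUE),
               (2 * f_a + 1 * f_b) / 3)
})

# independent evaluation of the printed triple-sum MCC formula
oracle_mcc <- function(C) {
  K <- nrow(C)
  num <- 0
  for (k in 1:K) for (l in 1:K) for (m in 1:K) {
    num <- num + C[k, k] * C[l, m] - C[k, l] * C[m, k]
  }
  d1 <- 0
  d2 <- 0
  for (k in 1:K) {
    d1 <- d1 + sum(C[k, ]) * sum(C[setdiff(1:K, k), ])
    d2 <- d2 + sum(C[, k]) * sum(C[, setdiff(1:K, k)])
  }
  if (d1 == 0 || d2 == 0) return(0)
  num / (sqrt(d1) * sqrt(d2))
}

test_that("multiclass MCC equals the printed-formula oracle", {
  expect_equal(mcc_multiclass(diag(c(5, 3, 2))), 1)
  # everything predicted as one class: convention 0
  C1 <- matrix(c(5, 0, 0, 3, 0, 0, 2, 0, 0), 3, byrow = TRUE)
  expect_equal(mcc_multiclass(C1), 0)
  C <- matrix(c(5, 1, 0, 1, 5, 1, 0, 1, 5), 3, byrow = TRUE)
  expect_equal(mcc_multiclass(C), oracle_mcc(C))
  # random confusion matrices agree with the oracle and stay in [-1, 1]
  set.seed(21)
  for (i in 1:20) {
    Cr <- matrix(rpois(9, 5), 3)
    expect_equal(mcc_multiclass(Cr), oracle_mcc(Cr), tolerance = 1e-12)
    expect_gte(mcc_multiclass(Cr), -1)
    expect_lte(mcc_multiclass(Cr), 1)
  }
})

test_that("multiclass MCC reduces to the binary closed form when K = 2", {
  set.seed(4)
  for (i in 1:10) {
    C <- matrix(rpois(4, 8) + 1, 2)
    tp <- C[2, 2]; tn <- C[1, 1]; fn <- C[2, 1]; fp <- C[1, 2]
    binary <- (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(mcc_multiclass(C), binary, tolerance = 1e-12)
  }
})

test_that("one-vs-rest relabeling is an indicator", {
  y <- c("G", "L", "N")
  expect_equal(one_vs_rest(y, "G"), c(1L, 0L, 0L))
  expect_equal(sum(one_vs_rest(y, "G") == 0), 2)
  expect_equal(one_vs_rest(c(1L, 0L), 1L), c(1L, 0L)) # idempotent on binary
})

# O(n^2) threshold-enumeration oracle for average precision
oracle_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  rec <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    r <- sum(labels[sel]) / sum(labels)
    ap <- ap + (r - rec) * prec
    rec <- r
  }
  ap
}

test_that("average precision matches forced cases and the oracle", {
  expect_equal(average_precision(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(.9, .1), c(0, 1)), 0.5)
  set.seed(6)
  for (i in 1:10) {
    s <- round(runif(50), 2) # rounded scores force ties
    y <- rbinom(50, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    expect_equal(average_precision(s, y), oracle_ap(s, y),
                 tolerance = 1e-12)
    expect_gte(average_precision(s, y), 0)
    expect_lte(average_precision(s, y), 1)
  }
})

test_that("score orientation is an involution compatible with AP", {
  expect_equal(orient_scores(0.2, higher_is_positive = FALSE), 0.8)
  s <- runif(20)
  expect_equal(orient_scores(orient_scores(s, FALSE), FALSE), s)
  y <- rbinom(20, 1, .5)
  if (sum(y) == 0) y[1] <- 1
  expect_equal(average_precision(orient_scores(s, FALSE), y),
               average_precision(1 - s, y))
})

test_that("evaluate_predictions ties the metrics together", {
  set.seed(9)
  prob <- matrix(runif(60), 20)
  prob <- prob / rowSums(prob)
  colnames(prob) <- c("GOF", "LOF", "NEUTRAL")
  y <- sample(colnames(prob), 20, replace = TRUE)
  rep <- evaluate_predictions(prob, y)
  expect_equal(nrow(rep$per_class), 3)
  expect_true(all(rep$per_class$ap >= 0 & rep$per_class$ap <= 1,
                  na.rm = TRUE))
  expect_gte(rep$overall$macro_f1, 0)
})
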