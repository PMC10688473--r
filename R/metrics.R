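#' Precision, recall and F1 over prediction sets
#'
#' Set-based definitions: with `y` the set of predicted (sample, label)
#' pairs and `y'` the set of true pairs, precision is `|y ∩ y'| / |y|`,
#' recall is `|y ∩ y'| / |y'|`, and F1 their harmonic mean. Empty
#' denominators yield 0.
#'
#' @param y_pred,y_true Character vectors of predicted and true labels
#'   aligned by position (the sample index forms the pair), or, when
#'   `positive` is given, treated as binary with `positive` the label of
#'   interest.
#' @param positive Optional label defining a one-vs-rest task; when `NULL`
#'   every (sample, label) pair counts.
#'
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
#' @examples
#' precision_recall_f1(c("a", "a", "b"), c("a", "b", "b"))
precision_recall_f1 <- function(y_pred, y_true, positive = NULL) {
  abort_if(length(y_pred) != length(y_true),
           "`y_pred` and `y_true` must have equal length")
  if (!is.null(positive)) {
    pred_set <- which(y_pred == positive)
    true_set <- which(y_true == positive)
    inter <- length(intersect(pred_set, true_set))
    n_pred <- length(pred_set)
    n_true <- length(true_set)
  } else {
    inter <- sum(y_pred == y_true)
    n_pred <- length(y_pred)
    n_true <- length(y_true)
  }
  precision <- if (n_pred == 0) 0 else inter / n_pred
  recall <- if (n_true == 0) 0 else inter / n_true
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Macro-averaged F1 score
#'
#' The unweighted mean of per-class one-vs-rest F1 scores over the label
#' set; `weighted = TRUE` instead weights each class by its true support
#' (a support-weighted variant some implementations report).
#'
#' @param y_pred,y_true Label vectors of equal length.
#' @param classes Label set `L`; defaults to the union of observed labels.
#' @param weighted Weight classes by support instead of averaging equally.
#'
#' @return A single number in `[0, 1]`.
#' @export
macro_f1 <- function(y_pred, y_true, classes = NULL, weighted = FALSE) {
  classes <- classes %||% sort(unique(c(y_pred, y_true)))
  abort_if(length(classes) < 1, "need at least one class")
  f1s <- vapply(classes, function(cl) {
    precision_recall_f1(y_pred, y_true, positive = cl)[["f1"]]
  }, numeric(1))
  if (weighted) {
    w <- vapply(classes, function(cl) sum(y_true == cl), numeric(1))
    if (sum(w) == 0) return(0)
    sum(w * f1s) / sum(w)
  } else {
    mean(f1s)
  }
}

#' Build a confusion matrix with a fixed class order
#'
#' @param y_pred,y_true Label vectors.
#' @param classes Class order for rows (true) and columns (predicted).
#' @return Integer K x K matrix, `C[k, l]` = samples of true class `k`
#'   predicted as class `l`.
#' @export
confusion_matrix <- function(y_pred, y_true, classes = NULL) {
  classes <- classes %||% sort(unique(c(y_pred, y_true)))
  table(factor(y_true, levels = classes),
        factor(y_pred, levels = classes)) |>
    unclass()
}

#' Generalized multiclass Matthews correlation coefficient
#'
#' The Gorodkin generalization of the MCC computed from a K x K confusion
#' matrix: the covariance between true and predicted assignments divided by
#' the geometric mean of their variances. Returns 0 when the denominator is
#' undefined (for example when every prediction falls in one class).
#'
#' @param C Confusion matrix from [confusion_matrix()] (true in rows,
#'   predicted in columns).
#'
#' @return A single number in `[-1, 1]`.
#' @export
mcc_multiclass <- function(C) {
  C <- as.matrix(C)
  abort_if(nrow(C) != ncol(C), "confusion matrix must be square")
  n <- sum(C)
  abort_if(n < 1, "empty confusion matrix")
  t_k <- rowSums(C) # true counts per class
  p_k <- colSums(C) # predicted counts per class
  cov_tp <- sum(diag(C)) * n - sum(t_k * p_k)
  cov_tt <- n^2 - sum(t_k^2)
  cov_pp <- n^2 - sum(p_k^2)
  if (cov_tt == 0 || cov_pp == 0) return(0)
  cov_tp / sqrt(cov_tt * cov_pp)
}

#' One-vs-rest relabeling
#'
#' @param y Label vector.
#' @param class The class relabeled as 1; everything else becomes 0.
#' @return Integer vector of 0/1.
#' @export
one_vs_rest <- function(y, class) {
  as.integer(y == class)
}

#' Average precision
#'
#' `AP = sum_n (recall_n - recall_{n-1}) * precision_n` over thresholds
#' placed at each distinct score in descending order (tied scores are
#' grouped into a single threshold).
#'
#' @param scores Numeric scores, higher means more positive.
#' @param labels Binary labels (0/1) aligned with `scores`.
#'
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' average_precision(c(.9, .8, .1), c(1, 1, 0))
average_precision <- function(scores, labels) {
  abort_if(length(scores) != length(labels), "lengths differ")
  abort_if(!all(labels %in% c(0, 1)), "`labels` must be 0/1")
  abort_if(sum(labels) == 0, "need at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  n_pos <- sum(y)
  # cumulative counts at each threshold = end of each tie group
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[grp_end]
  npred <- grp_end
  precision <- tp / npred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Orient prediction scores so that higher means positive
#'
#' Tools with inverted conventions (lower-is-damaging scores, or a
#' neutrality probability used against a pathogenic positive class) are
#' made comparable by replacing each score `s` with `1 - s`.
#'
#' @param scores Numeric scores.
#' @param higher_is_positive `TRUE` if the native convention already points
#'   the right way; `FALSE` applies the `1 - s` transform.
#' @return Oriented scores.
#' @export
orient_scores <- function(scores, higher_is_positive = TRUE) {
  if (higher_is_positive) scores else 1 - scores
}

#' Per-class evaluation report
#'
#' For each class: one-vs-rest average precision (using that class's
#' predicted probability as the score), one-vs-rest F1, and the one-vs-rest
#' binary MCC, alongside the multiclass macro-F1 and Gorodkin MCC.
#'
#' @param prob Matrix or data frame of class probabilities (columns named
#'   by class).
#' @param y_true True labels.
#' @return List with `per_class` tibble and `overall` tibble.
#' @export
evaluate_predictions <- function(prob, y_true) {
  prob <- as.matrix(prob)
  classes <- colnames(prob)
  abort_if(is.null(classes), "`prob` needs class column names")
  y_pred <- classes[max.col(prob, ties.method = "first")]
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    bin <- one_vs_rest(y_true, cl)
    prf <- precision_recall_f1(y_pred, y_true, positive = cl)
    Cb <- confusion_matrix(as.character(one_vs_rest(y_pred, cl)),
                           as.character(bin), classes = c("0", "1"))
    tibble::tibble(
      class = cl,
      ap = if (sum(bin) > 0) average_precision(prob[, cl], bin) else NA_real_,
      precision = prf[["precision"]], recall = prf[["recall"]],
      f1 = prf[["f1"]],
      mcc = mcc_multiclass(Cb)
    )
  }))
  overall <- tibble::tibble(
    macro_f1 = macro_f1(y_pred, y_true, classes),
    mcc = mcc_multiclass(confusion_matrix(y_pred, y_true, classes)),
    accuracy = mean(y_pred == y_true),
    n = length(y_true)
  )
  list(per_class = per_class, overall = overall)
}
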