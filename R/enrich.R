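#' Fisher's exact enrichment of a binary feature in a variant class
#'
#' Forms the 2x2 table of (target class vs background) by (feature present
#' vs absent), computes the two-sided exact p-value (hypergeometric
#' enumeration, as in [stats::fisher.test()]) and the sample odds ratio
#' `ad/bc`. When a zero cell would make the odds ratio 0 or infinite, the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and the row
#' is flagged; the p-value always comes from the uncorrected table.
#'
#' @param feature Logical (or 0/1) vector: feature present per variant.
#'   `NA` values are dropped with their labels.
#' @param labels Class label per variant.
#' @param target_class The class whose enrichment is tested.
#' @param background `"rest"` (all other classes) or `"other_class"` with
#'   `other` naming a single comparison class (e.g. GOF vs LOF with neutral
#'   variants excluded).
#' @param other Comparison class when `background = "other_class"`.
#' @param alpha Significance level used for the `significant` flag after
#'   adjustment (filled by [enrichment_table()]).
#'
#' @return One-row tibble of class data: counts `a` (target & feature),
#'   `b` (target & no feature), `c` (background & feature), `d`, plus
#'   `odds_ratio`, `log_odds`, `p`, `zero_cell_corrected`, `undefined`.
#' @export
fisher_enrichment <- function(feature, labels, target_class,
                              background = c("rest", "other_class"),
                              other = NULL, alpha = 0.05) {
  background <- match.arg(background)
  keep <- !is.na(feature)
  feature <- as.logical(feature[keep])
  labels <- labels[keep]
  in_target <- labels == target_class
  in_bg <- if (background == "rest") !in_target else {
    abort_if(is.null(other), "`other` required for background='other_class'")
    labels == other
  }
  a <- sum(in_target & feature)
  b <- sum(in_target & !feature)
  c_ <- sum(in_bg & feature)
  d <- sum(in_bg & !feature)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  undefined <- (a + b == 0) || (c_ + d == 0) || (a + c_ == 0) || (b + d == 0)
  if (undefined) {
    p <- 1
    or <- NA_real_
    corrected <- FALSE
  } else {
    p <- fisher.test(tab)$p.value
    corrected <- (a == 0 || b == 0 || c_ == 0 || d == 0)
    or <- if (corrected) {
      (a + .5) * (d + .5) / ((b + .5) * (c_ + .5))
    } else {
      a * d / (b * c_)
    }
  }
  tibble::tibble(
    class = target_class, a = a, b = b, c = c_, d = d,
    odds_ratio = or, log_odds = log(or), p = p,
    zero_cell_corrected = corrected, undefined = undefined
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values are `min_{j >= i} m p_(j) / j`, capped at 1 (the
#' standard step-up FDR procedure); rejection flags compare the adjusted
#' values to `alpha`.
#'
#' @param p Numeric vector of p-values.
#' @param alpha FDR level for the rejection flags.
#' @return Tibble with `p`, `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj, significant = adj < alpha)
}

#' One-sided Welch comparison of a continuous feature between classes
#'
#' Welch's unequal-variance two-sample t-test, one-sided in the stated
#' direction (`"greater"` tests mean(a) > mean(b)).
#'
#' @param values_a,values_b Numeric samples (>= 2 values each).
#' @param direction `"greater"` or `"less"`.
#' @return Tibble with `statistic`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_continuous <- function(values_a, values_b,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  abort_if(length(values_a) < 2 || length(values_b) < 2,
           "need at least two values per group")
  ht <- t.test(values_a, values_b, alternative = direction,
               var.equal = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, mean_a = mean(values_a), mean_b = mean(values_b)
  )
}

#' Class-wise enrichment table over many binary features
#'
#' Runs [fisher_enrichment()] for every (feature, class) combination and
#' applies the Benjamini-Hochberg correction across the whole family.
#'
#' @param features Tibble/data frame of logical (or 0/1) feature columns.
#' @param labels Class label per row.
#' @param classes Classes to test (default: all observed).
#' @param background,other,alpha Passed to [fisher_enrichment()] /
#'   [bh_adjust()].
#' @return Tibble of class `enrichment_table`, one row per feature x class.
#' @export
enrichment_table <- function(features, labels, classes = NULL,
                             background = "rest", other = NULL,
                             alpha = 0.05) {
  classes <- classes %||% sort(unique(labels))
  rows <- purrr::map_dfr(names(features), function(fn) {
    purrr::map_dfr(classes, function(cl) {
      oth <- if (identical(background, "other_class")) {
        other %||% setdiff(classes, cl)[1]
      } else NULL
      dplyr::mutate(
        fisher_enrichment(features[[fn]], labels, cl,
                          background = background, other = oth,
                          alpha = alpha),
        feature = fn, .before = 1
      )
    })
  })
  adj <- bh_adjust(rows$p, alpha = alpha)
  rows$p_adjusted <- adj$p_adjusted
  rows$significant <- adj$significant & !rows$undefined
  class(rows) <- c("enrichment_table", class(rows))
  rows
}

#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$log_odds))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_odds, y = .data$feature,
                                   fill = .data$class,
                                   alpha = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log odds ratio", y = NULL,
                  title = "Per-class feature enrichment") +
    ggplot2::theme_minimal()
}
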