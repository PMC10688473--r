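#' Default candidate distribution families for score calibration
#'
#' Continuous families suitable for classifier scores on `[0, 1]`: beta,
#' normal, logistic, gamma, lognormal and `[0, 1]`-truncated normal. The
#' list is an argument everywhere it is used, so it can be restricted or
#' extended.
#'
#' @return Character vector of family names.
#' @export
calibration_families <- function() {
  c("beta", "normal", "logistic", "gamma", "lognormal", "truncnorm")
}

# density / cdf / quantile of the [0,1]-truncated normal
dtnorm01 <- function(x, mean, sd) {
  z <- pnorm(1, mean, sd) - pnorm(0, mean, sd)
  ifelse(x >= 0 & x <= 1, dnorm(x, mean, sd) / z, 0)
}
ptnorm01 <- function(q, mean, sd) {
  lo <- pnorm(0, mean, sd)
  z <- pnorm(1, mean, sd) - lo
  pmin(pmax((pnorm(q, mean, sd) - lo) / z, 0), 1)
}
qtnorm01 <- function(p, mean, sd) {
  lo <- pnorm(0, mean, sd)
  z <- pnorm(1, mean, sd) - lo
  qnorm(lo + p * z, mean, sd)
}

fit_one_family <- function(x, family) {
  eps <- 1e-6
  switch(family,
    beta = {
      xb <- pmin(pmax(x, eps), 1 - eps)
      f <- fitdistrplus::fitdist(xb, "beta")
      list(params = as.list(f$estimate), pfun = "pbeta", qfun = "qbeta")
    },
    normal = {
      f <- fitdistrplus::fitdist(x, "norm")
      list(params = as.list(f$estimate), pfun = "pnorm", qfun = "qnorm")
    },
    logistic = {
      f <- fitdistrplus::fitdist(x, "logis")
      list(params = as.list(f$estimate), pfun = "plogis", qfun = "qlogis")
    },
    gamma = {
      xg <- pmax(x, eps)
      f <- fitdistrplus::fitdist(xg, "gamma")
      list(params = as.list(f$estimate), pfun = "pgamma", qfun = "qgamma")
    },
    lognormal = {
      xl <- pmax(x, eps)
      f <- fitdistrplus::fitdist(xl, "lnorm")
      list(params = as.list(f$estimate), pfun = "plnorm", qfun = "qlnorm")
    },
    truncnorm = {
      nll <- function(par) {
        if (par[2] <= 0) return(Inf)
        -sum(log(pmax(dtnorm01(x, par[1], par[2]), 1e-300)))
      }
      o <- optim(c(mean(x), max(sd(x), 1e-3)), nll)
      list(params = list(mean = o$par[1], sd = o$par[2]),
           pfun = "ptnorm01", qfun = "qtnorm01")
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

calib_pfun <- function(name) {
  if (name == "ptnorm01") return(ptnorm01)
  get(name, mode = "function", envir = asNamespace("stats"))
}
calib_qfun <- function(name) {
  if (name == "qtnorm01") return(qtnorm01)
  get(name, mode = "function", envir = asNamespace("stats"))
}

#' Select the best-fitting score distribution by Kolmogorov-Smirnov p-value
#'
#' Fits each candidate family to the scores by maximum likelihood, runs the
#' one-sample KS goodness-of-fit test against the fitted distribution, and
#' selects the family with the highest KS p-value. KS p-values are not
#' corrected for the estimated parameters (which makes them conservative);
#' they are used only to rank candidate fits.
#'
#' @param scores Numeric scores, at least 5, typically in `[0, 1]`.
#' @param families Candidate family names, see [calibration_families()].
#'
#' @return List of class `score_fit`: `family`, `params` (named list),
#'   `ks_pvalue`, `ks_statistic`, `n`, and the per-family fit table
#'   `candidates`.
#' @export
#' @examples
#' fit <- fit_best_distribution(rbeta(500, 2, 8))
#' fit$family
fit_best_distribution <- function(scores, families = calibration_families()) {
  scores <- scores[!is.na(scores)]
  abort_if(length(scores) < 5, "need at least 5 scores")
  abort_if(sd(scores) == 0, "scores are constant; no distribution fits")
  fits <- purrr::map(families, function(fam) {
    # fitdistrplus prints optimizer failures; keep them out of the console
    fit <- tryCatch(
      suppressWarnings(suppressMessages({
        utils::capture.output(res <- fit_one_family(scores, fam))
        res
      })),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    ks <- tryCatch(
      suppressWarnings(do.call(ks.test, c(list(scores, calib_pfun(fit$pfun)),
                                          fit$params))),
      error = function(e) NULL
    )
    if (is.null(ks)) return(NULL)
    list(family = fam, params = fit$params, qfun = fit$qfun,
         pvalue = ks$p.value, stat = unname(ks$statistic))
  })
  fits <- purrr::compact(fits)
  abort_if(length(fits) == 0, "no candidate family could be fitted")
  candidates <- tibble::tibble(
    family = purrr::map_chr(fits, "family"),
    ks_pvalue = purrr::map_dbl(fits, "pvalue"),
    ks_statistic = purrr::map_dbl(fits, "stat")
  )
  best <- fits[[which.max(candidates$ks_pvalue)]]
  structure(
    list(family = best$family, params = best$params, qfun = best$qfun,
         ks_pvalue = best$pvalue, ks_statistic = best$stat,
         n = length(scores), candidates = candidates),
    class = "score_fit"
  )
}

#' Central interval of a fitted score distribution
#'
#' The central `level` interval `[F^-1((1-level)/2), F^-1(1-(1-level)/2)]`
#' of the fitted distribution, clipped to `[0, 1]` (scores are
#' probabilities, so mass outside the unit interval is an artefact of the
#' family).
#'
#' @param fit A `score_fit` from [fit_best_distribution()], or a family
#'   name with `params` supplied.
#' @param level Interval mass, default 0.95.
#' @param params Named list of parameters when `fit` is a family name.
#' @return Named numeric vector `c(low, high)`.
#' @export
dist_interval <- function(fit, level = 0.95, params = NULL) {
  abort_if(level <= 0 || level >= 1, "`level` must be in (0, 1)")
  if (is.character(fit)) {
    qmap <- c(beta = "qbeta", normal = "qnorm", logistic = "qlogis",
              gamma = "qgamma", lognormal = "qlnorm",
              truncnorm = "qtnorm01", uniform = "qunif")
    abort_if(!fit %in% names(qmap), paste("unknown family:", fit))
    qf <- calib_qfun(qmap[[fit]])
    pars <- params
  } else {
    qf <- calib_qfun(fit$qfun)
    pars <- fit$params
  }
  a <- (1 - level) / 2
  lo <- do.call(qf, c(list(a), pars))
  hi <- do.call(qf, c(list(1 - a), pars))
  c(low = max(0, min(1, lo)), high = max(0, min(1, hi)))
}

#' Global and per-gene prediction intervals
#'
#' For every (gene, class) with at least `min_n` scores, fits the score
#' distribution by KS selection and emits a gene-scoped interval; for all
#' other (gene, class) pairs the interval defaults to the global fit over
#' all scores of that class. Global entries are always emitted.
#'
#' @param predictions Tibble with columns `gene`, `class`, `score`.
#' @param min_n Minimum per-gene sample size for a gene-scoped fit.
#' @param level Interval mass.
#' @param families Candidate families.
#' @return Tibble of class `calibration_table`: `scope` ("global" or the
#'   gene symbol), `class`, `family`, `params` (JSON), `low`, `high`, `n`.
#' @export
gene_intervals <- function(predictions, min_n = 5, level = 0.95,
                           families = calibration_families()) {
  abort_if(!all(c("gene", "class", "score") %in% names(predictions)),
           "`predictions` needs columns gene, class, score")
  entry <- function(scope, class, scores) {
    fit <- tryCatch(fit_best_distribution(scores, families),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    iv <- dist_interval(fit, level = level)
    tibble::tibble(
      scope = scope, class = class, family = fit$family,
      params = as.character(jsonlite::toJSON(fit$params,
                                             auto_unbox = TRUE, digits = NA)),
      low = iv[["low"]], high = iv[["high"]], n = fit$n
    )
  }
  global <- purrr::map_dfr(split(predictions, predictions$class), function(d) {
    entry("global", d$class[1], d$score)
  })
  abort_if(nrow(global) == 0, "no class had enough scores for a global fit")
  per_gene <- predictions |>
    dplyr::group_by(.data$gene, .data$class) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(d) {
      if (nrow(d) >= min_n) {
        e <- entry(d$gene[1], d$class[1], d$score)
        if (!is.null(e)) return(e)
      }
      # fall back to the global entry for this class
      g <- global[global$class == d$class[1], , drop = FALSE]
      if (nrow(g) == 0) return(NULL)
      dplyr::mutate(g, scope = d$gene[1])
    })
  out <- dplyr::bind_rows(global, per_gene)
  class(out) <- c("calibration_table", class(out))
  out
}

#' @method print score_fit
#' @export
print.score_fit <- function(x, ...) {
  cat(sprintf("<score_fit> %s (n=%d, KS p=%.3g)\n  params: %s\n",
              x$family, x$n, x$ks_pvalue,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @method glance score_fit
#' @export
glance.score_fit <- function(x, ...) {
  tibble::tibble(family = x$family, ks_pvalue = x$ks_pvalue,
                 ks_statistic = x$ks_statistic, n = x$n)
}

#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$scope, ymin = .data$low,
                               ymax = .data$high, colour = .data$class)) +
    ggplot2::geom_linerange(position = ggplot2::position_dodge(width = .5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "score interval", x = NULL,
                  title = "Per-scope score intervals") +
    ggplot2::theme_minimal()
}
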