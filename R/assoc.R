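#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-prior-penalized log-likelihood
#' `l(beta) + 0.5 log |I(beta)|` by Newton iteration with the Firth-adjusted
#' score `U*_j = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ij`, where `h_i` are
#' the hat-matrix diagonals. The penalty keeps estimates finite even under
#' complete separation, which is what makes the method suitable for rare
#' variants in skewed case-control cohorts. Wald p-values are reported per
#' coefficient; a penalized likelihood-ratio test is available for a single
#' coefficient via `firth_lrt()`.
#'
#' @param X Design matrix including the intercept column; full column rank.
#' @param y Binary 0/1 outcome, not constant.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the adjusted score.
#'
#' @return Object of class `firth_fit`: tibble `coefficients` (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `loglik` (penalized),
#'   `converged`, `iter`, `n`.
#' @export
#' @examples
#' X <- cbind(1, c(0, 0, 1, 1))
#' y <- c(0, 1, 0, 1)
#' firth_fit(X, y)
firth_fit <- function(X, y, max_iter = 50L, tol = 1e-6) {
  X <- as.matrix(X)
  abort_if(length(y) != nrow(X), "X and y sizes differ")
  abort_if(!all(y %in% c(0, 1)), "`y` must be binary 0/1")
  abort_if(var(y) == 0, "`y` is constant")
  abort_if(qr(X)$rank < ncol(X), "`X` is not full column rank")
  p_dim <- ncol(X)
  beta <- rep(0, p_dim)

  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * w, X)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }

  converged <- FALSE
  iter <- 0L
  ll_old <- pen_loglik(beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * w, X)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) break
    # hat diagonals of W^(1/2) X I^-1 X' W^(1/2)
    h <- rowSums((X %*% info_inv) * X) * w
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (max(abs(U)) < tol) {
      converged <- TRUE
      break
    }
    step <- drop(info_inv %*% U)
    # step-halving to guarantee ascent of the penalized likelihood
    for (half in 0:10) {
      cand <- beta + step / 2^half
      ll_new <- pen_loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
    }
    beta <- cand
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X * w, X)
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  terms <- colnames(X) %||% paste0("x", seq_len(p_dim))
  structure(
    list(
      coefficients = tibble::tibble(
        term = terms, estimate = beta, std_error = se,
        statistic = z, p_value = 2 * pnorm(-abs(z))
      ),
      loglik = as.numeric(ll_old), converged = converged, iter = iter,
      n = length(y), X = X, y = y
    ),
    class = "firth_fit"
  )
}

#' Penalized likelihood-ratio test for one coefficient
#'
#' Refits the Firth model with the named term dropped and compares twice
#' the penalized log-likelihood difference to a chi-square with one degree
#' of freedom.
#'
#' @param fit A [firth_fit()] result.
#' @param term Coefficient name to test.
#' @return Tibble with `term`, `chisq`, `p_value`.
#' @export
firth_lrt <- function(fit, term) {
  idx <- match(term, fit$coefficients$term)
  abort_if(is.na(idx), "unknown term")
  fit0 <- firth_fit(fit$X[, -idx, drop = FALSE], fit$y)
  chisq <- max(0, 2 * (fit$loglik - fit0$loglik))
  tibble::tibble(term = term, chisq = chisq,
                 p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' @method tidy firth_fit
#' @export
tidy.firth_fit <- function(x, ...) {
  dplyr::mutate(x$coefficients, odds_ratio = exp(.data$estimate))
}

#' @method glance firth_fit
#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged,
                 iter = x$iter, n = x$n)
}

#' @method print firth_fit
#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("<firth_fit> n=%d, converged=%s (%d iterations)\n",
              x$n, x$converged, x$iter))
  print(x$coefficients)
  invisible(x)
}

#' Phenome-wide Firth association scan
#'
#' Tests every (variant, phenotype) pair with Firth-penalized logistic
#' regression adjusted for the supplied covariates. Phenotypes with fewer
#' than `min_cases` cases are skipped entirely; results with a minor allele
#' count (computed on the analyzed, non-missing samples) below `min_mac`,
#' or that failed to converge, are flagged as excluded. The Bonferroni
#' significance threshold is `alpha` divided by the number of phenotypes
#' actually tested (0.05 over 1075 phenotypes gives 4.65e-5). For smaller
#' replication cohorts the filters are typically relaxed to
#' `min_cases = 20, min_mac = 10`.
#'
#' @param genotypes Tibble: `sample_id` plus one 0/1/2 column per variant
#'   (`NA` allowed).
#' @param phenotypes Tibble: `sample_id` plus one binary column per
#'   phenotype.
#' @param covariates Tibble: `sample_id` plus numeric covariate columns,
#'   or `NULL`.
#' @param min_cases Minimum case count for a phenotype to be tested.
#' @param min_mac Minimum minor allele count for a result to pass filters.
#' @param alpha Family-wise significance level.
#'
#' @return Object of class `phewas_result`: tibble `results` (one row per
#'   tested pair with `beta`, `se`, `odds_ratio`, `p`, `mac`, `n_cases`,
#'   `n_controls`, `converged`, `passed_filters`), `threshold`,
#'   `n_phenotypes_tested`.
#' @export
run_phewas <- function(genotypes, phenotypes, covariates = NULL,
                       min_cases = 50, min_mac = 20, alpha = 0.05) {
  abort_if(!"sample_id" %in% names(genotypes) ||
             !"sample_id" %in% names(phenotypes),
           "genotype and phenotype tables need a sample_id column")
  ids <- genotypes$sample_id
  abort_if(!identical(sort(ids), sort(phenotypes$sample_id)),
           "sample ids of genotypes and phenotypes are misaligned")
  phenotypes <- phenotypes[match(ids, phenotypes$sample_id), ]
  if (!is.null(covariates)) {
    abort_if(!identical(sort(ids), sort(covariates$sample_id)),
             "sample ids of covariates are misaligned")
    covariates <- covariates[match(ids, covariates$sample_id), ]
    cov_mat <- as.matrix(covariates[, setdiff(names(covariates), "sample_id"),
                                    drop = FALSE])
  } else {
    cov_mat <- NULL
  }
  var_cols <- setdiff(names(genotypes), "sample_id")
  phe_cols <- setdiff(names(phenotypes), "sample_id")
  tested_phe <- phe_cols[vapply(phe_cols, function(ph) {
    sum(phenotypes[[ph]] == 1, na.rm = TRUE) >= min_cases
  }, logical(1))]
  results <- purrr::map_dfr(tested_phe, function(ph) {
    purrr::map_dfr(var_cols, function(v) {
      g <- genotypes[[v]]
      y <- phenotypes[[ph]]
      keep <- !is.na(g) & !is.na(y)
      if (!is.null(cov_mat)) keep <- keep & stats::complete.cases(cov_mat)
      g <- g[keep]
      y <- y[keep]
      mac <- min(sum(g), sum(2 - g))
      X <- cbind(intercept = 1, genotype = g,
                 if (!is.null(cov_mat)) cov_mat[keep, , drop = FALSE])
      fit <- tryCatch(firth_fit(X, y), error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble::tibble(
          variant = v, phenotype = ph, n_cases = sum(y),
          n_controls = sum(1 - y), mac = mac, beta = NA_real_,
          se = NA_real_, odds_ratio = NA_real_, p = NA_real_,
          converged = FALSE, passed_filters = FALSE
        ))
      }
      co <- fit$coefficients[fit$coefficients$term == "genotype", ]
      tibble::tibble(
        variant = v, phenotype = ph, n_cases = sum(y),
        n_controls = sum(1 - y), mac = mac,
        beta = co$estimate, se = co$std_error,
        odds_ratio = exp(co$estimate), p = co$p_value,
        converged = fit$converged,
        passed_filters = fit$converged && mac >= min_mac
      )
    })
  })
  structure(
    list(results = results,
         threshold = alpha / max(length(tested_phe), 1L),
         n_phenotypes_tested = length(tested_phe),
         alpha = alpha, min_cases = min_cases, min_mac = min_mac),
    class = "phewas_result"
  )
}

#' Bonferroni threshold over tested phenotypes
#'
#' @param alpha Family-wise level.
#' @param n_phenotypes Number of phenotypes tested.
#' @return `alpha / n_phenotypes`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 1075)
bonferroni_threshold <- function(alpha = 0.05, n_phenotypes) {
  abort_if(n_phenotypes < 1, "`n_phenotypes` must be >= 1")
  alpha / n_phenotypes
}

#' @method tidy phewas_result
#' @export
tidy.phewas_result <- function(x, ...) {
  dplyr::mutate(x$results, significant = .data$passed_filters &
                  !is.na(.data$p) & .data$p < x$threshold)
}

#' @method glance phewas_result
#' @export
glance.phewas_result <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$results),
    n_phenotypes_tested = x$n_phenotypes_tested,
    threshold = x$threshold,
    n_significant = sum(tidy(x)$significant)
  )
}

#' @method print phewas_result
#' @export
print.phewas_result <- function(x, ...) {
  cat(sprintf(
    "<phewas_result> %d tests over %d phenotypes; Bonferroni p < %.3g\n",
    nrow(x$results), x$n_phenotypes_tested, x$threshold))
  invisible(x)
}

#' @method autoplot phewas_result
#' @export
autoplot.phewas_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype,
                                   y = -log10(.data$p),
                                   colour = .data$variant,
                                   shape = .data$passed_filters)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Phenome-wide Firth associations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
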