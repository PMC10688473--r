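#' Hyperparameter search space for the gradient-boosted ensemble
#'
#' Defines sampling bounds for the tuned quantities: learning rate
#' (log-uniform), maximum tree depth, minimum child weight, L1/L2
#' regularization (log-uniform), number of boosting rounds, row/column
#' subsampling, and the ensemble size (5 to 31 members, tuned alongside
#' the member hyperparameters).
#'
#' @param learning_rate,max_depth,min_child_weight,reg_alpha,reg_lambda,
#'   n_estimators,subsample,colsample_bytree,ensemble_size Length-2
#'   (lower, upper) bounds.
#' @return Object of class `search_space` (a named list of bounds).
#' @export
search_space <- function(learning_rate = c(1e-3, 0.3),
                         max_depth = c(3L, 12L),
                         min_child_weight = c(1, 50),
                         reg_alpha = c(1e-8, 10),
                         reg_lambda = c(1e-8, 10),
                         n_estimators = c(50L, 500L),
                         subsample = c(0.5, 1),
                         colsample_bytree = c(0.5, 1),
                         ensemble_size = c(5L, 31L)) {
  sp <- list(
    learning_rate = learning_rate, max_depth = max_depth,
    min_child_weight = min_child_weight, reg_alpha = reg_alpha,
    reg_lambda = reg_lambda, n_estimators = n_estimators,
    subsample = subsample, colsample_bytree = colsample_bytree,
    ensemble_size = ensemble_size
  )
  for (nm in names(sp)) {
    abort_if(length(sp[[nm]]) != 2 || sp[[nm]][1] > sp[[nm]][2],
             paste("invalid bounds for", nm))
  }
  structure(sp, class = "search_space")
}

sample_config <- function(space) {
  lu <- function(b) exp(runif(1, log(b[1]), log(b[2])))
  list(
    learning_rate = lu(space$learning_rate),
    max_depth = sample(space$max_depth[1]:space$max_depth[2], 1L),
    min_child_weight = runif(1, space$min_child_weight[1],
                             space$min_child_weight[2]),
    reg_alpha = lu(space$reg_alpha),
    reg_lambda = lu(space$reg_lambda),
    n_estimators = sample(space$n_estimators[1]:space$n_estimators[2], 1L),
    subsample = runif(1, space$subsample[1], space$subsample[2]),
    colsample_bytree = runif(1, space$colsample_bytree[1],
                             space$colsample_bytree[2]),
    ensemble_size = sample(space$ensemble_size[1]:space$ensemble_size[2], 1L)
  )
}

#' Default member hyperparameters for the final ensemble
#'
#' Moderate regularization and depth limits with 27 ensemble members (the
#' default final architecture); any entry can be overridden.
#' @param ... Overrides.
#' @return Config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    learning_rate = 0.1, max_depth = 6L, min_child_weight = 5,
    reg_alpha = 0.1, reg_lambda = 1, n_estimators = 150L,
    subsample = 0.8, colsample_bytree = 0.8, ensemble_size = 27L
  )
  utils::modifyList(cfg, list(...))
}

GL_CLASSES <- c("GOF", "LOF", "NEUTRAL")

fit_one_member <- function(mat, labels_int, config, seed) {
  params <- list(
    objective = "multi:softprob", num_class = 3L,
    eta = config$learning_rate, max_depth = config$max_depth,
    min_child_weight = config$min_child_weight,
    alpha = config$reg_alpha, lambda = config$reg_lambda,
    subsample = config$subsample,
    colsample_bytree = config$colsample_bytree,
    nthread = 1L, verbosity = 0L, seed = seed
  )
  withr::with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(mat, label = labels_int)
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = config$n_estimators, verbose = 0)
  })
}

#' Train the soft-voting ensemble of gradient-boosted tree classifiers
#'
#' Trains `config$ensemble_size` boosted-tree members on the (typically
#' oversampled) training matrix, differing only by random seed; the
#' ensemble prediction is the unweighted mean of the member probability
#' vectors ("soft voting"). Members are trained on the same rows — the
#' seed controls row/column subsampling inside each member, so members do
#' differ.
#'
#' @param mat Numeric training matrix (from [transform_features()]).
#' @param labels Class labels (`GOF`/`LOF`/`NEUTRAL` by default).
#' @param config Hyperparameter list, see [default_config()].
#' @param classes Class order of the probability output.
#' @param seed Base seed; member `i` uses `seed + i`.
#' @param preprocessor Optional fitted preprocessor stored for prediction
#'   from raw tables.
#' @return Object of class `gl_ensemble`.
#' @export
train_ensemble <- function(mat, labels, config = default_config(),
                           classes = GL_CLASSES, seed = 1L,
                           preprocessor = NULL) {
  n_members <- config$ensemble_size
  abort_if(n_members < 1 || n_members > 64,
           "`ensemble_size` must be between 1 and 64")
  abort_if(!all(labels %in% classes), "labels outside the class set")
  labels_int <- match(labels, classes) - 1L
  members <- lapply(seq_len(n_members), function(i) {
    fit_one_member(mat, labels_int, config, as.integer(seed) + i)
  })
  structure(
    list(members = members, config = config, classes = classes,
         feature_names = colnames(mat), n_members = n_members,
         preprocessor = preprocessor, seed = as.integer(seed)),
    class = "gl_ensemble"
  )
}

#' @method print gl_ensemble
#' @export
print.gl_ensemble <- function(x, ...) {
  cat(sprintf("<gl_ensemble> %d boosted-tree members, %d features, classes: %s\n",
              x$n_members, length(x$feature_names),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

check_columns <- function(model, mat) {
  abort_if(is.null(colnames(mat)) ||
             !identical(colnames(mat), model$feature_names),
           paste0("feature columns do not match training order; expected: ",
                  paste(model$feature_names, collapse = ", ")))
}

#' Predict class probabilities with the soft-voting ensemble
#'
#' @param object A [train_ensemble()] model.
#' @param newdata Numeric matrix with the training column order, or a raw
#'   feature table when the model stores a preprocessor.
#' @param ... Unused.
#' @return Tibble with one probability column per class (rows sum to 1).
#' @method predict gl_ensemble
#' @export
predict.gl_ensemble <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && !is.null(object$preprocessor)) {
    newdata <- transform_features(newdata, object$preprocessor)
  }
  newdata <- as.matrix(newdata)
  check_columns(object, newdata)
  dtest <- xgboost::xgb.DMatrix(newdata)
  acc <- matrix(0, nrow(newdata), length(object$classes))
  for (m in object$members) {
    p <- predict(m, dtest)
    acc <- acc + matrix(p, nrow = nrow(newdata), byrow = FALSE)
  }
  acc <- acc / object$n_members
  acc <- acc / rowSums(acc)
  colnames(acc) <- object$classes
  tibble::as_tibble(acc)
}

#' Per-feature attribution of ensemble predictions
#'
#' Exact tree-path additive attributions (TreeSHAP) computed per member
#' and per class, averaged over the ensemble members. For every member,
#' the attributions plus the bias term reproduce that member's margin
#' output, so the averaged attributions are additive for the ensemble
#' margin as well.
#'
#' @param model A [train_ensemble()] model.
#' @param mat Numeric matrix in the training column order.
#' @return List of class `gl_attribution`: `contrib` — a list (one per
#'   class) of n x (features + bias) matrices averaged over members —
#'   and `mean_abs` — a tibble of mean absolute attribution per feature
#'   and class.
#' @export
attribute_ensemble <- function(model, mat) {
  mat <- as.matrix(mat)
  check_columns(model, mat)
  dtest <- xgboost::xgb.DMatrix(mat)
  n_class <- length(model$classes)
  acc <- NULL
  for (m in model$members) {
    ctr <- predict(m, dtest, predcontrib = TRUE)
    # n x class x (p+1) array -> per-class list of n x (p+1) matrices
    if (is.array(ctr) && length(dim(ctr)) == 3) {
      ctr <- lapply(seq_len(n_class), function(k) {
        matrix(ctr[, k, ], nrow = nrow(mat))
      })
    } else if (!is.list(ctr)) {
      p1 <- ncol(mat) + 1L
      ctr <- lapply(seq_len(n_class), function(k) {
        ctr[, ((k - 1) * p1 + 1):(k * p1), drop = FALSE]
      })
    }
    if (is.null(acc)) acc <- lapply(ctr, function(x) x * 0)
    acc <- Map(`+`, acc, ctr)
  }
  acc <- lapply(acc, function(x) {
    x <- x / model$n_members
    colnames(x) <- c(model$feature_names, "bias")
    x
  })
  names(acc) <- model$classes
  mean_abs <- purrr::map_dfr(model$classes, function(cl) {
    m <- acc[[cl]][, model$feature_names, drop = FALSE]
    tibble::tibble(class = cl, feature = colnames(m),
                   mean_abs_attribution = colMeans(abs(m)))
  })
  structure(list(contrib = acc, mean_abs = mean_abs),
            class = "gl_attribution")
}

#' @method tidy gl_ensemble
#' @export
tidy.gl_ensemble <- function(x, newdata = NULL, ...) {
  abort_if(is.null(newdata), "supply `newdata` to attribute against")
  attribute_ensemble(x, newdata)$mean_abs
}

#' @method glance gl_ensemble
#' @export
glance.gl_ensemble <- function(x, ...) {
  tibble::tibble(n_members = x$n_members,
                 n_features = length(x$feature_names),
                 learning_rate = x$config$learning_rate,
                 max_depth = x$config$max_depth,
                 n_estimators = x$config$n_estimators)
}

# gene-grouped fold assignment balancing class counts greedily
gene_folds <- function(genes, labels, n_folds, max_retry = 10L) {
  gene_class <- table(genes, labels)
  g_names <- rownames(gene_class)
  for (attempt in seq_len(max_retry)) {
    perm <- sample.int(length(g_names))
    sizes <- rowSums(gene_class)[perm]
    ord <- perm[order(sizes, decreasing = TRUE)]
    fold_counts <- matrix(0, n_folds, ncol(gene_class))
    fold_of <- integer(length(g_names))
    for (gi in ord) {
      # add the gene to the currently smallest fold
      target <- which.min(rowSums(fold_counts))
      fold_counts[target, ] <- fold_counts[target, ] + gene_class[gi, ]
      fold_of[gi] <- target
    }
    fold_id <- fold_of[match(genes, g_names)]
    ok <- all(vapply(seq_len(n_folds), function(f) {
      length(unique(labels[fold_id == f])) == length(unique(labels))
    }, logical(1)))
    if (ok) return(fold_id)
  }
  warning("could not build folds containing every class; using last attempt",
          call. = FALSE)
  fold_id
}

evaluate_config <- function(config, mat, labels, fold_id, classes) {
  scores <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    bal <- oversample_classes(mat[tr, , drop = FALSE], labels[tr])
    mdl <- train_ensemble(bal$mat, bal$labels,
                          utils::modifyList(config, list(ensemble_size = 1L)),
                          classes = classes, seed = f)
    prob <- predict(mdl, mat[!tr, , drop = FALSE])
    pred <- classes[max.col(as.matrix(prob), ties.method = "first")]
    macro_f1(pred, labels[!tr], classes)
  }, numeric(1))
  mean(scores)
}

#' Gene-grouped nested cross-validation with random hyperparameter search
#'
#' Outer loop: `n_outer` gene-grouped folds (no gene contributes variants
#' to more than one fold). Inner loop: on each outer-training portion,
#' `n_inner` gene-grouped folds score `n_trials` randomly sampled
#' configurations by inner-CV macro-F1; preprocessing — including the
#' random oversampling to class balance — is fitted inside each inner
#' training portion, so no information flows from any evaluation fold into
#' a fitted component. The inner winner is refit (as a full soft-voting
#' ensemble) on the outer-training portion and scored on the outer-test
#' portion.
#'
#' Inner-loop configs are evaluated with single-member models to keep the
#' search affordable; the winning config's `ensemble_size` is honoured in
#' the refit.
#'
#' @param table Feature table (data frame) or numeric matrix.
#' @param labels Class labels.
#' @param genes Gene per sample (grouping factor of the folds).
#' @param space A [search_space()].
#' @param schema Optional [feature_schema()] when `table` is a data frame.
#' @param n_outer,n_inner Fold counts.
#' @param n_trials Random-search trials per outer fold (the full-scale
#'   procedure uses 200).
#' @param classes Class order.
#' @param seed Integer seed.
#' @return Object of class `gl_nested_cv`: tibble `outer_scores`
#'   (`fold`, `macro_f1`, `mcc`), `best_config` (the winning config of the
#'   best outer fold), `configs` per fold.
#' @export
nested_cv <- function(table, labels, genes, space = search_space(),
                      schema = NULL, n_outer = 5L, n_inner = 5L,
                      n_trials = 200L, classes = GL_CLASSES, seed = 1L) {
  abort_if(length(labels) != length(genes), "labels/genes length mismatch")
  withr::with_seed(as.integer(seed), {
    outer_id <- gene_folds(genes, labels, n_outer)
    per_fold <- lapply(seq_len(n_outer), function(f) {
      tr <- outer_id != f
      tbl_tr <- if (is.data.frame(table)) table[tr, , drop = FALSE]
      else table[tr, , drop = FALSE]
      pre <- if (is.data.frame(table)) fit_preprocessor(tbl_tr, schema)
      else NULL
      mat_tr <- if (is.null(pre)) as.matrix(tbl_tr)
      else transform_features(tbl_tr, pre)
      lab_tr <- labels[tr]
      inner_id <- gene_folds(genes[tr], lab_tr, n_inner)
      trials <- lapply(seq_len(n_trials), function(i) {
        cfg <- sample_config(space)
        list(config = cfg,
             score = evaluate_config(cfg, mat_tr, lab_tr, inner_id, classes))
      })
      best <- trials[[which.max(vapply(trials, `[[`, numeric(1), "score"))]]
      bal <- oversample_classes(mat_tr, lab_tr)
      mdl <- train_ensemble(bal$mat, bal$labels, best$config,
                            classes = classes, seed = f)
      mat_te <- if (is.null(pre)) as.matrix(table[!tr, , drop = FALSE])
      else transform_features(table[!tr, , drop = FALSE], pre)
      prob <- predict(mdl, mat_te)
      pred <- classes[max.col(as.matrix(prob), ties.method = "first")]
      list(
        fold = f,
        macro_f1 = macro_f1(pred, labels[!tr], classes),
        mcc = mcc_multiclass(confusion_matrix(pred, labels[!tr], classes)),
        config = best$config, inner_score = best$score
      )
    })
    outer_scores <- tibble::tibble(
      fold = vapply(per_fold, `[[`, numeric(1), "fold"),
      macro_f1 = vapply(per_fold, `[[`, numeric(1), "macro_f1"),
      mcc = vapply(per_fold, `[[`, numeric(1), "mcc"),
      inner_score = vapply(per_fold, `[[`, numeric(1), "inner_score")
    )
    best_fold <- which.max(outer_scores$macro_f1)
    structure(
      list(outer_scores = outer_scores,
           best_config = per_fold[[best_fold]]$config,
           configs = lapply(per_fold, `[[`, "config")),
      class = "gl_nested_cv"
    )
  })
}

#' @method print gl_nested_cv
#' @export
print.gl_nested_cv <- function(x, ...) {
  cat(sprintf("<gl_nested_cv> %d outer folds; median macro-F1 %.3f, median MCC %.3f\n",
              nrow(x$outer_scores), median(x$outer_scores$macro_f1),
              median(x$outer_scores$mcc)))
  invisible(x)
}

#' @method tidy gl_nested_cv
#' @export
tidy.gl_nested_cv <- function(x, ...) x$outer_scores

#' @method glance gl_nested_cv
#' @export
glance.gl_nested_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$outer_scores),
    median_macro_f1 = median(x$outer_scores$macro_f1),
    median_mcc = median(x$outer_scores$mcc),
    best_ensemble_size = x$best_config$ensemble_size
  )
}

#' @method autoplot gl_nested_cv
#' @export
autoplot.gl_nested_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$outer_scores,
                            cols = c("macro_f1", "mcc"),
                            names_to = "metric", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$score,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "outer fold", y = "score",
                  title = "Nested cross-validation outer-fold scores") +
    ggplot2::theme_minimal()
}

#' Serialize / restore an ensemble model directory
#'
#' Writes the config and class order as JSON plus one model file per
#' member; `read_ensemble()` restores the model.
#'
#' @param model A `gl_ensemble`.
#' @param dir Directory path (created if needed).
#' @return `write_ensemble()` returns `dir` invisibly.
#' @export
write_ensemble <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = model$config, classes = model$classes,
         feature_names = model$feature_names, n_members = model$n_members,
         seed = model$seed),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA
  )
  for (i in seq_along(model$members)) {
    xgboost::xgb.save(model$members[[i]],
                      file.path(dir, sprintf("member_%02d.ubj", i)))
  }
  if (!is.null(model$preprocessor)) {
    write_preprocessor(model$preprocessor, file.path(dir, "preprocessor.json"))
  }
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "ensemble.json"),
                             simplifyVector = TRUE)
  members <- lapply(seq_len(meta$n_members), function(i) {
    xgboost::xgb.load(file.path(dir, sprintf("member_%02d.ubj", i)))
  })
  pre_path <- file.path(dir, "preprocessor.json")
  structure(
    list(members = members, config = as.list(meta$config),
         classes = meta$classes, feature_names = meta$feature_names,
         n_members = meta$n_members,
         preprocessor = if (file.exists(pre_path)) read_preprocessor(pre_path),
         seed = meta$seed),
    class = "gl_ensemble"
  )
}
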