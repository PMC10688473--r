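#' Build a feature schema
#'
#' The schema names every model-input feature, its kind, and its
#' missing-value policy. Categorical, ordinal and binary features are
#' imputed with the constant -1; continuous features with the training-set
#' median (the two policies the preprocessing pipeline supports). An
#' optional categorization rule (see [categorize()]) drives the enrichment
#' binning of continuous features.
#'
#' @param name Character vector of feature names (unique).
#' @param kind One of `"continuous"`, `"categorical"`, `"binary"` per
#'   feature (recycled if scalar).
#' @param missing_policy `"constant_minus1"` or `"train_median"`; defaults
#'   by kind (continuous -> median, others -> -1).
#' @return Tibble of class `feature_schema`.
#' @export
feature_schema <- function(name, kind = "continuous", missing_policy = NULL) {
  abort_if(anyDuplicated(name) > 0, "feature names must be unique")
  kind <- rep_len(kind, length(name))
  abort_if(!all(kind %in% c("continuous", "categorical", "binary")),
           "unknown feature kind")
  if (is.null(missing_policy)) {
    missing_policy <- ifelse(kind == "continuous",
                             "train_median", "constant_minus1")
  }
  missing_policy <- rep_len(missing_policy, length(name))
  abort_if(!all(missing_policy %in% c("constant_minus1", "train_median")),
           "unknown missing policy")
  out <- tibble::tibble(name = name, kind = kind,
                        missing_policy = missing_policy)
  class(out) <- c("feature_schema", class(out))
  out
}

# infer a schema from column types when the user supplies none
default_schema <- function(table, exclude = c("variant_id", "label", "gene")) {
  cols <- setdiff(names(table), exclude)
  kind <- vapply(cols, function(nm) {
    x <- table[[nm]]
    if (is.character(x) || is.factor(x)) "categorical"
    else if (all(x %in% c(0, 1, NA))) "binary"
    else "continuous"
  }, character(1))
  feature_schema(cols, kind)
}

#' Fit the feature preprocessor on training data only
#'
#' Learns, from the training table alone: ordinal codes for categorical
#' features (sorted distinct training categories mapped to 0, 1, ...),
#' per-feature training medians for continuous imputation, and the list of
#' zero-variance features (evaluated after imputation) that will be dropped
#' from both train and test. Nothing from any later `transform` input can
#' alter the fitted state.
#'
#' @param train_table Data frame of training features (non-feature columns
#'   ignored via the schema).
#' @param schema A [feature_schema()]; inferred from column types if `NULL`.
#'
#' @return Object of class `variant_preprocessor` with fields
#'   `schema`, `category_maps`, `medians`, `dropped`, `feature_order`.
#' @export
fit_preprocessor <- function(train_table, schema = NULL) {
  abort_if(nrow(train_table) == 0, "training table is empty")
  schema <- schema %||% default_schema(train_table)
  missing_cols <- setdiff(schema$name, names(train_table))
  abort_if(length(missing_cols) > 0,
           paste("schema features absent from table:",
                 paste(missing_cols, collapse = ", ")))
  category_maps <- list()
  medians <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- train_table[[nm]]
    if (schema$kind[i] == "categorical") {
      category_maps[[nm]] <- sort(unique(as.character(x[!is.na(x)])))
    }
    if (schema$missing_policy[i] == "train_median") {
      medians[[nm]] <- median(as.numeric(x), na.rm = TRUE)
    }
  }
  pre <- structure(
    list(schema = schema, category_maps = category_maps,
         medians = medians, dropped = character(0),
         feature_order = schema$name),
    class = "variant_preprocessor"
  )
  # zero-variance features, evaluated after imputation, are dropped
  mat <- transform_features(train_table, pre)
  zv <- colnames(mat)[apply(mat, 2, function(v) max(v) == min(v))]
  pre$dropped <- zv
  pre$feature_order <- setdiff(schema$name, zv)
  pre
}

#' Transform a feature table into a model-ready numeric matrix
#'
#' Applies the fitted encoder: categorical values map to their ordinal
#' training codes (unseen categories become missing and fall into the -1
#' path), missing values are imputed with -1 or the training median
#' according to the schema policy, dropped zero-variance columns are
#' removed, and the column order recorded at fit time is enforced. The
#' output never contains missing values.
#'
#' @param table Feature data frame (train or test).
#' @param pre A fitted [fit_preprocessor()] object.
#' @return Numeric matrix with columns `pre$feature_order`.
#' @export
transform_features <- function(table, pre) {
  abort_if(!inherits(pre, "variant_preprocessor"),
           "`pre` must come from fit_preprocessor()")
  schema <- pre$schema
  cols <- lapply(seq_len(nrow(schema)), function(i) {
    nm <- schema$name[i]
    x <- table[[nm]]
    abort_if(is.null(x), paste("missing feature column:", nm))
    if (schema$kind[i] == "categorical") {
      x <- match(as.character(x), pre$category_maps[[nm]]) - 1
    } else {
      x <- as.numeric(x)
    }
    if (schema$missing_policy[i] == "train_median") {
      x[is.na(x)] <- pre$medians[[nm]]
    } else {
      x[is.na(x)] <- -1
    }
    x
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- schema$name
  mat[, pre$feature_order, drop = FALSE]
}

#' Random oversampling to exact class balance
#'
#' Minority classes are resampled with replacement until every class count
#' equals the majority-class count. The majority class rows are passed
#' through untouched. Only ever apply this to training folds; oversampling
#' test data inflates every metric.
#'
#' @param mat Numeric feature matrix (rows = samples).
#' @param labels Class label per row; every class must be present.
#' @return List with `mat`, `labels` (balanced), and `index` (row indices
#'   into the input).
#' @export
oversample_classes <- function(mat, labels) {
  counts <- table(labels) # factor labels keep empty levels, which error
  abort_if(any(counts == 0), "every class must have at least one sample")
  target <- max(counts)
  idx <- unlist(lapply(names(counts), function(cl) {
    rows <- which(labels == cl)
    extra <- target - length(rows)
    c(rows, if (extra > 0) sample(rows, extra, replace = TRUE))
  }))
  list(mat = mat[idx, , drop = FALSE], labels = labels[idx], index = idx)
}

#' Categorize a continuous or probabilistic feature value
#'
#' Implements the binning rules used by the enrichment analysis:
#' * `threshold` rules split at a fixed cutoff, lower label below it —
#'   Grantham substitution scores are `conservative` below 100 and
#'   `radical` at or above 100; relative solvent accessibility is `buried`
#'   strictly below 0.20 and `exposed` otherwise.
#' * `median_split` rules compare to a supplied reference median (e.g. the
#'   proteome-wide median residue contact count): values at or above the
#'   median are `high`, below are `low`.
#' * `probability` rules use a 0.5 cutoff, with values >= 0.5 on the
#'   positive side.
#' Missing values always categorize as `"missing"`.
#'
#' @param value Numeric vector.
#' @param rule A rule created by `rule_threshold()`, `rule_median_split()`
#'   or `rule_probability()`.
#' @return Character vector of categories.
#' @export
categorize <- function(value, rule) {
  abort_if(!inherits(rule, "categorization_rule"), "`rule` is not a rule")
  out <- rep("missing", length(value))
  ok <- !is.na(value)
  out[ok] <- switch(rule$type,
    threshold = ifelse(value[ok] < rule$threshold,
                       rule$labels[1], rule$labels[2]),
    median_split = ifelse(value[ok] < rule$reference_median, "low", "high"),
    probability = ifelse(value[ok] >= 0.5,
                         rule$labels[2], rule$labels[1])
  )
  out
}

#' @rdname categorize
#' @param threshold Cutoff; values strictly below get `labels[1]`.
#' @param labels Length-2 labels, low side first.
#' @export
rule_threshold <- function(threshold, labels = c("low", "high")) {
  structure(list(type = "threshold", threshold = threshold, labels = labels),
            class = "categorization_rule")
}

#' @rdname categorize
#' @param reference_median Proteome-wide reference median.
#' @export
rule_median_split <- function(reference_median) {
  structure(list(type = "median_split", reference_median = reference_median),
            class = "categorization_rule")
}

#' @rdname categorize
#' @export
rule_probability <- function(labels = c("negative", "positive")) {
  structure(list(type = "probability", labels = labels),
            class = "categorization_rule")
}

#' Grantham-score and RSA convenience rules
#' @rdname categorize
#' @export
rule_grantham <- function() {
  rule_threshold(100, c("conservative", "radical"))
}

#' @rdname categorize
#' @export
rule_rsa <- function() {
  rule_threshold(0.20, c("buried", "exposed"))
}

#' Serialize / restore a fitted preprocessor as JSON
#'
#' @param pre A `variant_preprocessor`.
#' @param path File path.
#' @return `write_preprocessor()` returns `path` invisibly;
#'   `read_preprocessor()` the restored object.
#' @export
write_preprocessor <- function(pre, path) {
  jsonlite::write_json(
    list(schema = as.data.frame(pre$schema),
         category_maps = pre$category_maps, medians = pre$medians,
         dropped = pre$dropped, feature_order = pre$feature_order),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sch <- tibble::as_tibble(x$schema)
  class(sch) <- c("feature_schema", class(sch))
  structure(
    list(schema = sch,
         category_maps = as.list(x$category_maps),
         medians = as.list(x$medians),
         dropped = as.character(x$dropped),
         feature_order = as.character(x$feature_order)),
    class = "variant_preprocessor"
  )
}
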