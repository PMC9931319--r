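#' Cohort-level exclusion filters
#'
#' Removes stays below the minimum age of 16 and stays carrying a pre-computed
#' exclusion flag (column `excluded`, logical, optional) representing upstream
#' eligibility criteria computed outside this package. Row order is otherwise
#' preserved.
#'
#' @param cohort A cohort tibble with an `age` column (and optionally an
#'   `excluded` flag column).
#' @return The filtered tibble, without the `excluded` column.
#' @export
apply_cohort_filters <- function(cohort) {
  if (!"age" %in% names(cohort)) {
    stop("cohort lacks required column 'age'", call. = FALSE)
  }
  keep <- is.na(cohort$age) | cohort$age >= 16
  if ("excluded" %in% names(cohort)) {
    keep <- keep & !(cohort$excluded %in% TRUE)
    cohort$excluded <- NULL
  }
  cohort[keep, , drop = FALSE]
}

#' Recode obfuscated ages
#'
#' Ages strictly above 89 years are recoded to 90 (the convention for ages
#' obfuscated under HIPAA provisions); all other ages pass through unchanged.
#' Idempotent.
#'
#' @param age Numeric vector of ages in years.
#' @return Numeric vector.
#' @export
recode_age <- function(age) {
  stopifnot(is.numeric(age))
  ifelse(!is.na(age) & age > 89, 90, age)
}

#' Fit imputation and standardization statistics
#'
#' Computes per-feature imputation values and standardization statistics to be
#' frozen from a training set. Imputation values are per-column means of the
#' designated table (the full cohort under `full_dataset_mean`, the training
#' split under `train_mean`, or training medians under `train_median`);
#' centering and scaling statistics are the mean and population standard
#' deviation of the *training* table after imputation.
#'
#' The `full_dataset_mean` default matches the primary analysis convention of
#' imputing from the pooled data; note this lets test-environment rows
#' influence imputation values (a mild form of information leakage that the
#' alternative `train_*` modes avoid).
#'
#' @param train Training cohort tibble.
#' @param full Full cohort tibble (required for `full_dataset_mean`).
#' @param mode Imputation mode.
#' @param features Feature columns (defaults to the 14 model inputs).
#' @return A `preprocessor_stats` object.
#' @export
fit_preprocessor <- function(train, full = NULL,
                             mode = c("full_dataset_mean", "train_mean",
                                      "train_median"),
                             features = model_features()) {
  mode <- match.arg(mode)
  if (nrow(train) == 0) stop("training table is empty", call. = FALSE)
  missing_cols <- setdiff(features, names(train))
  if (length(missing_cols) > 0) {
    stop("training table lacks feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  source_tbl <- switch(mode,
    full_dataset_mean = {
      if (is.null(full)) {
        stop("mode 'full_dataset_mean' requires the full table", call. = FALSE)
      }
      full
    },
    train
  )
  agg <- if (mode == "train_median") {
    function(x) stats::median(x, na.rm = TRUE)
  } else {
    function(x) mean(x, na.rm = TRUE)
  }
  impute_value <- vapply(features, function(f) agg(as.numeric(source_tbl[[f]])),
                         numeric(1))

  center <- numeric(length(features))
  scale <- numeric(length(features))
  names(center) <- names(scale) <- features
  for (f in features) {
    x <- as.numeric(train[[f]])
    x[is.na(x)] <- impute_value[[f]]
    center[[f]] <- mean(x)
    # population (uncorrected) standard deviation
    scale[[f]] <- sqrt(mean((x - center[[f]])^2))
    if (!is.finite(scale[[f]]) || scale[[f]] <= 0) {
      stop("feature '", f, "' is degenerate (zero variance) in train",
           call. = FALSE)
    }
  }
  structure(
    list(features = features, impute_value = impute_value,
         center = center, scale = scale, imputation_mode = mode),
    class = "preprocessor_stats"
  )
}

#' Apply frozen preprocessing statistics
#'
#' Replaces missing feature values by the frozen imputation values, then
#' standardizes each feature as `(x - center) / scale`. Identifier, grouping,
#' and label columns are carried through untransformed.
#'
#' @param table Cohort tibble.
#' @param stats A `preprocessor_stats` object from [fit_preprocessor()].
#' @return A tibble with standardized feature columns.
#' @export
transform_cohort <- function(table, stats) {
  stopifnot(inherits(stats, "preprocessor_stats"))
  missing_cols <- setdiff(stats$features, names(table))
  if (length(missing_cols) > 0) {
    stop("table lacks feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (f in stats$features) {
    x <- as.numeric(table[[f]])
    x[is.na(x)] <- stats$impute_value[[f]]
    table[[f]] <- (x - stats$center[[f]]) / stats$scale[[f]]
  }
  table
}

#' Extract the numeric design matrix for modelling
#'
#' @param table A (transformed) cohort tibble.
#' @param features Feature columns.
#' @return A numeric matrix.
#' @keywords internal
feature_matrix <- function(table, features = model_features()) {
  as.matrix(table[, features, drop = FALSE])
}

#' Serialize preprocessing statistics to YAML for audit
#'
#' @param stats A `preprocessor_stats` object.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_preprocessor <- function(stats, path) {
  yaml::write_yaml(
    list(
      features = stats$features,
      impute_value = as.list(stats$impute_value),
      center = as.list(stats$center),
      scale = as.list(stats$scale),
      imputation_mode = stats$imputation_mode
    ),
    path
  )
  invisible(path)
}
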