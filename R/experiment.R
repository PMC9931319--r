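#' Environment grouping of a cohort
#'
#' Adds an `env` column naming each stay's environment under one of the
#' supported grouping keys: individual hospital, US geographic region, or the
#' finer region x beds-band x teaching-status pooling.
#'
#' @param cohort A cohort tibble.
#' @param environment_key One of `"hospital"`, `"region"`,
#'   `"region_beds_teaching"`.
#' @return The cohort with an `env` character column.
#' @export
assign_environment <- function(cohort,
                               environment_key = c("hospital", "region",
                                                   "region_beds_teaching")) {
  environment_key <- match.arg(environment_key)
  cohort$env <- switch(environment_key,
    hospital = cohort$hospital_id,
    region = cohort$region,
    region_beds_teaching = paste(cohort$region, cohort$beds_band,
                                 ifelse(cohort$teaching, "teaching",
                                        "nonteaching"),
                                 sep = "/")
  )
  cohort
}

#' Subsample an environment without replacement
#'
#' @param cohort A cohort tibble with an environment column.
#' @param environment_id Environment to draw from.
#' @param n Number of rows to draw, uniformly without replacement.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param env_col Name of the environment column.
#' @return A tibble of exactly `n` rows.
#' @export
subsample_environment <- function(cohort, environment_id, n, seed,
                                  env_col = "env") {
  rows <- which(cohort[[env_col]] == environment_id)
  if (length(rows) < n) {
    stop("environment '", environment_id, "' has ", length(rows),
         " rows, fewer than the requested ", n, call. = FALSE)
  }
  set.seed(seed)
  cohort[sample(rows, n), , drop = FALSE]
}

#' Random train/validation split
#'
#' Disjoint, exhaustive split with `floor(fraction * n)` training rows.
#'
#' @param table A tibble.
#' @param fraction Training fraction (default 0.9).
#' @param seed Integer seed.
#' @return A list with elements `train` and `validation`.
#' @export
split_train_validation <- function(table, fraction = 0.9, seed = 1L) {
  stopifnot(nrow(table) > 0, fraction > 0, fraction < 1)
  set.seed(seed)
  n_train <- floor(fraction * nrow(table))
  idx <- sample(nrow(table), n_train)
  list(train = table[idx, , drop = FALSE],
       validation = table[-idx, , drop = FALSE])
}

#' Plan a cross-environment transfer experiment
#'
#' @param environment_key Grouping key, see [assign_environment()].
#' @param n_per_environment Rows drawn per environment and replicate (1631 for
#'   hospital-level and 5000 for region-level analyses by convention).
#' @param n_subsamples Replicates per train-test pair (default 100).
#' @param validation_fraction Held-out fraction of the training draw.
#' @param strength Penalty strength passed to [fit_risk_model()].
#' @param imputation_mode Passed to [fit_preprocessor()].
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return An `experiment_plan` object.
#' @export
experiment_plan <- function(environment_key = "hospital",
                            n_per_environment = if (environment_key == "region") 5000L else 1631L,
                            n_subsamples = 100L,
                            validation_fraction = 0.1,
                            strength = 1,
                            imputation_mode = "full_dataset_mean",
                            seed = 1L) {
  stopifnot(validation_fraction > 0, validation_fraction < 1,
            n_per_environment >= 1, n_subsamples >= 1)
  structure(
    list(environment_key = environment_key,
         n_per_environment = as.integer(n_per_environment),
         n_subsamples = as.integer(n_subsamples),
         validation_fraction = validation_fraction,
         strength = strength,
         imputation_mode = imputation_mode,
         seed = as.integer(seed)),
    class = "experiment_plan"
  )
}

# Independent reproducible integer seeds for every (cell, replicate, purpose).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Run the fixed-n cross-environment transfer experiment
#'
#' For every ordered (train environment, test environment) pair, including the
#' diagonal, and for each replicate: draw `n_per_environment` rows from the
#' training environment without replacement, split 90/10 into train and
#' validation, freeze the preprocessor and fit the penalized logistic model on
#' the training part, then evaluate the full metric suite on the validation
#' part and on a fresh draw of `n_per_environment` rows from the test
#' environment. The FNR threshold is the test draw's mortality rate.
#' Generalization gaps are test minus validation AUC / calibration slope.
#'
#' On the diagonal the test draw excludes the training draw's rows when the
#' environment is large enough; otherwise the validation part doubles as the
#' test set (flagged in the run log attribute).
#'
#' @param cohort A cohort tibble.
#' @param plan An [experiment_plan()].
#' @return A `transfer_matrix`: long tibble with columns `train_env`,
#'   `test_env`, `replicate`, `metric`, `value`, with the plan and an
#'   exclusion log stored as attributes.
#' @export
run_transfer_experiment <- function(cohort, plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  cohort <- assign_environment(cohort, plan$environment_key)
  envs <- sort(unique(cohort$env))
  sizes <- table(cohort$env)
  n <- plan$n_per_environment
  if (any(sizes < n)) {
    small <- names(sizes)[sizes < n]
    stop("environments smaller than n_per_environment: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  pairs <- expand.grid(train_env = envs, test_env = envs,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(pairs) * plan$n_subsamples
  seeds <- matrix(derive_seeds(plan$seed, 3L * n_cells), ncol = 3)

  log_notes <- character(0)
  results <- vector("list", n_cells)
  cell <- 0L
  for (p in seq_len(nrow(pairs))) {
    tr_env <- pairs$train_env[p]
    te_env <- pairs$test_env[p]
    tr_rows <- which(cohort$env == tr_env)
    te_rows_all <- which(cohort$env == te_env)
    for (r in seq_len(plan$n_subsamples)) {
      cell <- cell + 1L
      s <- seeds[cell, ]
      set.seed(s[1])
      draw_idx <- sample(tr_rows, n)
      draw <- cohort[draw_idx, , drop = FALSE]
      parts <- split_train_validation(draw, 1 - plan$validation_fraction, s[2])

      # test draw: fresh sample from the test environment, excluding the
      # training draw's rows on the diagonal when possible
      te_pool <- if (tr_env == te_env) setdiff(te_rows_all, draw_idx) else te_rows_all
      set.seed(s[3])
      if (length(te_pool) >= n) {
        test <- cohort[sample(te_pool, n), , drop = FALSE]
      } else if (tr_env == te_env) {
        test <- parts$validation
        log_notes <- c(log_notes, sprintf(
          "diagonal cell %s replicate %d: validation reused as test (environment too small for a disjoint draw)",
          tr_env, r))
      } else {
        test <- cohort[sample(te_pool, n), , drop = FALSE]
      }

      rep_metrics <- tryCatch({
        pre <- fit_preprocessor(parts$train, full = cohort,
                                mode = plan$imputation_mode)
        if (length(unique(parts$train$mortality)) < 2) {
          stop("single-class training subsample")
        }
        model <- fit_risk_model(feature_matrix(transform_cohort(parts$train, pre)),
                                parts$train$mortality,
                                strength = plan$strength, preprocessor = pre)
        val_risk <- predict_risk(model, parts$validation)
        test_risk <- predict_risk(model, test)
        threshold <- prevalence_threshold(test$mortality)
        val_m <- evaluate_predictions(parts$validation$mortality, val_risk,
                                      threshold = threshold)
        test_m <- evaluate_predictions(test$mortality, test_risk,
                                       race_group = test$race_group,
                                       threshold = threshold)
        tibble::tibble(
          metric = c("auc", "cs", "gap_auc", "gap_cs", "fnr", "threshold",
                     "fnr_minority", "fnr_majority", "disparity_fnr",
                     "cs_minority", "cs_majority", "disparity_cs",
                     "val_auc", "val_cs"),
          value = c(test_m$auc, test_m$cs,
                    generalization_gap(test_m$auc, val_m$auc),
                    generalization_gap(test_m$cs, val_m$cs),
                    test_m$fnr, threshold,
                    test_m$fnr_minority, test_m$fnr_majority,
                    test_m$disparity_fnr,
                    test_m$cs_minority, test_m$cs_majority,
                    test_m$disparity_cs,
                    val_m$auc, val_m$cs)
        )
      }, error = function(e) {
        log_notes <<- c(log_notes, sprintf(
          "cell %s->%s replicate %d excluded: %s",
          tr_env, te_env, r, conditionMessage(e)))
        NULL
      })
      if (!is.null(rep_metrics)) {
        rep_metrics$train_env <- tr_env
        rep_metrics$test_env <- te_env
        rep_metrics$replicate <- r
        results[[cell]] <- rep_metrics
      }
    }
  }
  out <- dplyr::bind_rows(results)[, c("train_env", "test_env", "replicate",
                                       "metric", "value")]
  attr(out, "plan") <- plan
  attr(out, "log") <- log_notes
  class(out) <- c("transfer_matrix", class(out))
  out
}

#' @export
print.transfer_matrix <- function(x, ...) {
  plan <- attr(x, "plan")
  cat("<transfer_matrix>",
      length(unique(x$train_env)), "x", length(unique(x$test_env)),
      "environments,", max(x$replicate), "replicates",
      sprintf("(n = %d per draw)\n", plan$n_per_environment))
  NextMethod()
}

#' Write and read a transfer matrix as long-format CSV
#'
#' @param matrix A `transfer_matrix`.
#' @param path File path.
#' @return The path / the tibble.
#' @export
write_transfer_matrix <- function(matrix, path) {
  readr::write_csv(matrix, path)
  invisible(path)
}

#' @rdname write_transfer_matrix
#' @export
read_transfer_matrix <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    train_env = readr::col_character(),
    test_env = readr::col_character(),
    replicate = readr::col_integer(),
    metric = readr::col_character(),
    value = readr::col_double()
  ))
  class(out) <- c("transfer_matrix", class(out))
  out
}
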