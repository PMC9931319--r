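#' Area under the ROC curve
#'
#' Probability that a uniformly random positive case is scored above a
#' uniformly random negative case, with ties counted as one half (midrank
#' convention).
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)) # 0.75
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]
  scores <- scores[keep]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope
#'
#' Slope of the logistic regression of observed binary outcomes on the logits
#' of the predicted risks (intercept included). A perfectly calibrated model
#' has slope 1; a slope below 1 indicates risk estimates that are too extreme
#' (overestimation for high-risk and underestimation for low-risk patients),
#' the typical signature of overfitting.
#'
#' @param labels Binary outcomes (0/1).
#' @param risks Predicted probabilities; clipped to
#'   `[1e-12, 1 - 1e-12]` before taking logits.
#' @return The slope, or `NA` if undefined (single class, constant logits, or
#'   a non-converged fit).
#' @export
calibration_slope <- function(labels, risks) {
  stopifnot(length(labels) == length(risks))
  keep <- !is.na(labels) & !is.na(risks)
  labels <- labels[keep]
  risks <- pmin(pmax(risks[keep], 1e-12), 1 - 1e-12)
  if (length(unique(labels)) < 2) return(NA_real_)
  lgt <- stats::qlogis(risks)
  if (stats::sd(lgt) < 1e-12) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(
      stats::glm(labels ~ lgt, family = stats::binomial())
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) return(NA_real_)
  unname(stats::coef(fit)[["lgt"]])
}

#' Generalization gap
#'
#' Metric value on the external test data minus the same metric on the
#' development (validation) data. Negative values mean the model degraded on
#' transfer.
#'
#' @param test_value,validation_value Metric values.
#' @return `test_value - validation_value`, `NA` if either is undefined.
#' @export
generalization_gap <- function(test_value, validation_value) {
  test_value - validation_value
}

#' Classification threshold at the test prevalence
#'
#' The mortality rate of the test environment, used as the risk threshold for
#' false-negative-rate computations (assumed known at deployment).
#'
#' @param test_labels Binary outcomes of the test environment.
#' @return Mean of the labels.
#' @export
prevalence_threshold <- function(test_labels) {
  test_labels <- test_labels[!is.na(test_labels)]
  if (length(test_labels) == 0) stop("no test labels supplied", call. = FALSE)
  mean(test_labels)
}

#' False negative rate at a risk threshold
#'
#' A stay is classified positive when its predicted risk is greater than or
#' equal to the threshold; the FNR is the fraction of truly positive stays
#' classified negative. Non-decreasing in the threshold.
#'
#' @param labels Binary outcomes.
#' @param risks Predicted probabilities.
#' @param threshold Classification threshold in `[0, 1]`.
#' @return FNR in `[0, 1]`, or `NA` if there are no positive labels.
#' @export
fnr_at_threshold <- function(labels, risks, threshold) {
  keep <- !is.na(labels) & !is.na(risks)
  labels <- labels[keep]
  risks <- risks[keep]
  pos <- labels == 1
  if (!any(pos)) return(NA_real_)
  mean(risks[pos] < threshold)
}

#' Between-group disparity of a metric
#'
#' Minority-group value minus majority-group value; 0 is the equitable ideal.
#' Antisymmetric under swapping the group labels.
#'
#' @param minority_value,majority_value Per-group metric values.
#' @return The signed difference, `NA` if either side is undefined.
#' @export
group_disparity <- function(minority_value, majority_value) {
  minority_value - majority_value
}

#' Percentage change relative to the training value
#'
#' `100 * (test - train) / |train|`; the absolute-value denominator keeps the
#' sign meaningful for negative training values.
#'
#' @param train_value,test_value Metric values.
#' @return Percent change, `NA` if the training value is 0 or undefined.
#' @export
percentage_change <- function(train_value, test_value) {
  out <- 100 * (test_value - train_value) / abs(train_value)
  out[!is.na(train_value) & train_value == 0] <- NA_real_
  out
}

#' Full metric set for one evaluation
#'
#' Computes the per-replicate metric suite on one evaluation set: AUC,
#' calibration slope, FNR at the test-prevalence threshold, per-group FNR and
#' calibration slopes, and the two disparity metrics. Metrics whose
#' preconditions fail (single-class data, an absent group) are `NA`.
#'
#' @param labels Binary outcomes.
#' @param risks Predicted probabilities.
#' @param race_group Character vector (`"minority"`/`"majority"`), or `NULL`
#'   to skip the fairness metrics.
#' @param threshold Classification threshold; defaults to the prevalence of
#'   `labels`.
#' @return A one-row tibble.
#' @export
evaluate_predictions <- function(labels, risks, race_group = NULL,
                                 threshold = NULL) {
  if (is.null(threshold)) threshold <- prevalence_threshold(labels)
  out <- tibble::tibble(
    auc = roc_auc(labels, risks),
    cs = calibration_slope(labels, risks),
    fnr = fnr_at_threshold(labels, risks, threshold),
    threshold = threshold,
    fnr_minority = NA_real_, fnr_majority = NA_real_,
    disparity_fnr = NA_real_,
    cs_minority = NA_real_, cs_majority = NA_real_,
    disparity_cs = NA_real_
  )
  if (!is.null(race_group)) {
    mino <- race_group == "minority"
    majo <- race_group == "majority"
    if (any(mino) && any(majo)) {
      out$fnr_minority <- fnr_at_threshold(labels[mino], risks[mino], threshold)
      out$fnr_majority <- fnr_at_threshold(labels[majo], risks[majo], threshold)
      out$disparity_fnr <- group_disparity(out$fnr_minority, out$fnr_majority)
      out$cs_minority <- calibration_slope(labels[mino], risks[mino])
      out$cs_majority <- calibration_slope(labels[majo], risks[majo])
      out$disparity_cs <- group_disparity(out$cs_minority, out$cs_majority)
    }
  }
  out
}

#' Pooled quartile summary of a transfer experiment
#'
#' Median, first and third quartile of every metric, pooled over all
#' train-test environment pairs and their replicates. Replicates where a
#' metric was undefined are dropped from that metric's summary, with counts
#' reported. Disparity metrics are additionally summarized in absolute value
#' (columns `abs_disparity_fnr`, `abs_disparity_cs`).
#'
#' @param matrix A `transfer_matrix` tibble from [run_transfer_experiment()].
#' @param off_diagonal_only Drop the train == test diagonal cells first.
#' @return A tibble: `metric`, `median`, `q1`, `q3`, `n`, `n_dropped`.
#' @export
aggregate_transfer <- function(matrix, off_diagonal_only = FALSE) {
  stopifnot(nrow(matrix) > 0)
  if (off_diagonal_only) {
    matrix <- dplyr::filter(matrix, .data$train_env != .data$test_env)
  }
  long <- matrix
  for (m in c("disparity_fnr", "disparity_cs")) {
    if (m %in% unique(long$metric)) {
      abs_rows <- dplyr::filter(long, .data$metric == m)
      abs_rows$metric <- paste0("abs_", m)
      abs_rows$value <- abs(abs_rows$value)
      long <- dplyr::bind_rows(long, abs_rows)
    }
  }
  long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      median = stats::median(.data$value, na.rm = TRUE),
      q1 = unname(stats::quantile(.data$value, 0.25, na.rm = TRUE)),
      q3 = unname(stats::quantile(.data$value, 0.75, na.rm = TRUE)),
      n = sum(!is.na(.data$value)),
      n_dropped = sum(is.na(.data$value)),
      .groups = "drop"
    )
}

#' Correlation between generalization gaps and dataset shift
#'
#' Pearson correlation, across environment pairs, between the per-pair mean
#' generalization gap (in AUC and in calibration slope) and the per-pair mean
#' MMD^2 dataset-shift statistic. Diagonal cells are excluded.
#'
#' @param matrix A `transfer_matrix` tibble.
#' @param shifts A `shift_matrix` tibble from [pairwise_shift_matrix()].
#' @return A tibble: `gap_metric`, `correlation`, `n_pairs`.
#' @export
gap_shift_correlation <- function(matrix, shifts) {
  gaps <- matrix |>
    dplyr::filter(.data$metric %in% c("gap_auc", "gap_cs"),
                  .data$train_env != .data$test_env) |>
    dplyr::group_by(.data$train_env, .data$test_env, .data$metric) |>
    dplyr::summarise(gap = mean(.data$value, na.rm = TRUE), .groups = "drop")
  # unordered-pair shift statistic looked up for both pair orders
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  shift_lookup <- stats::setNames(
    shifts$mean_mmd2, key(shifts$env_a, shifts$env_b)
  )
  gaps$mmd2 <- shift_lookup[key(gaps$train_env, gaps$test_env)]
  gaps |>
    dplyr::group_by(gap_metric = .data$metric) |>
    dplyr::summarise(
      correlation = {
        ok <- !is.na(.data$gap) & !is.na(.data$mmd2)
        if (sum(ok) < 3 || stats::sd(.data$gap[ok]) == 0 ||
            stats::sd(.data$mmd2[ok]) == 0) {
          NA_real_
        } else {
          stats::cor(.data$gap[ok], .data$mmd2[ok])
        }
      },
      n_pairs = sum(!is.na(.data$gap) & !is.na(.data$mmd2)),
      .groups = "drop"
    )
}
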