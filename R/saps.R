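#' @keywords internal
#' @importFrom rlang .data :=
"_PACKAGE"

#' Physiological feature registry
#'
#' The 12 physiological worst-value features (6 vitals, 6 labs) used by the
#' mortality model, in canonical column order, plus the two non-physiological
#' model inputs (age and the elective-surgery indicator).
#'
#' @return Character vector of column names.
#' @export
physiology_features <- function() {
  c(
    # vitals
    "hr", "sysbp", "temp", "gcs", "urineoutput", "pao2fio2",
    # labs
    "bun", "wbc", "potassium", "sodium", "bicarbonate", "bilirubin"
  )
}

#' @rdname physiology_features
#' @export
model_features <- function() {
  c("age", "elective_surgery", physiology_features())
}

#' @rdname physiology_features
#' @export
cohort_columns <- function() {
  c(
    "stay_id", "hospital_id", "region", "beds_band", "teaching",
    "age", "race_group", "elective_surgery",
    physiology_features(), "mortality"
  )
}

# SAPS II point bands (Le Gall et al. 1993, severity points per measurement
# band). Each row: lower bound (inclusive), upper bound (exclusive), points.
# Bands cover the whole real line; the zero-point band is the normal range,
# whose midpoint breaks ties between equally scored candidate measurements.
saps_point_bands <- list(
  hr = cbind(lo = c(-Inf, 40, 70, 120, 160), hi = c(40, 70, 120, 160, Inf),
             pts = c(11, 2, 0, 4, 7)),
  sysbp = cbind(lo = c(-Inf, 70, 100, 200), hi = c(70, 100, 200, Inf),
                pts = c(13, 5, 0, 2)),
  temp = cbind(lo = c(-Inf, 39), hi = c(39, Inf), pts = c(0, 3)),
  bun = cbind(lo = c(-Inf, 28, 84), hi = c(28, 84, Inf), pts = c(0, 6, 10)),
  wbc = cbind(lo = c(-Inf, 1, 20), hi = c(1, 20, Inf), pts = c(12, 0, 3)),
  potassium = cbind(lo = c(-Inf, 3, 5), hi = c(3, 5, Inf), pts = c(3, 0, 3)),
  sodium = cbind(lo = c(-Inf, 125, 145), hi = c(125, 145, Inf),
                 pts = c(5, 0, 1)),
  bicarbonate = cbind(lo = c(-Inf, 15, 20), hi = c(15, 20, Inf),
                      pts = c(6, 3, 0)),
  bilirubin = cbind(lo = c(-Inf, 4, 6), hi = c(4, 6, Inf), pts = c(0, 4, 9))
)

# Worseness direction per feature: "min" (lowest value is worst), or "points"
# (measurement in the highest-scoring SAPS II band is worst, ties broken by
# distance from the midpoint of the zero-point band). PaO2/FiO2 points are
# monotone decreasing in the ratio, so min-is-worst is exact for it.
worseness_direction <- function(feature_name) {
  if (feature_name %in% c("gcs", "urineoutput", "pao2fio2")) return("min")
  if (feature_name %in% names(saps_point_bands)) return("points")
  stop("no registered worseness direction for feature '", feature_name, "'",
       call. = FALSE)
}

saps_points <- function(values, feature_name) {
  bands <- saps_point_bands[[feature_name]]
  pts <- numeric(length(values))
  for (b in seq_len(nrow(bands))) {
    inside <- values >= bands[b, "lo"] & values < bands[b, "hi"]
    pts[inside] <- bands[b, "pts"]
  }
  pts
}

# Midpoint of the zero-point (normal) band; half-open bands at the extremes
# fall back to the finite endpoint.
normal_band_midpoint <- function(feature_name) {
  bands <- saps_point_bands[[feature_name]]
  zero <- bands[bands[, "pts"] == 0, , drop = FALSE][1, ]
  lo <- zero[["lo"]]
  hi <- zero[["hi"]]
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  (lo + hi) / 2
}

#' Worst-value aggregation of repeated measurements
#'
#' Reduces a stay's repeated measurements of one feature to the single worst
#' value in the SAPS II sense. Glasgow Coma Score and urine output take the
#' minimum; the remaining vitals and labs take the measurement falling in the
#' highest-scoring SAPS II severity band, breaking point ties by distance from
#' the midpoint of the normal (zero-point) band.
#'
#' @param measurements Numeric vector of repeated measurements for one stay.
#'   `NA` entries are dropped before aggregation.
#' @param feature_name One of [physiology_features()].
#' @return A single numeric value, or `NA` if no non-missing measurement is
#'   available.
#' @examples
#' worst_value_aggregate(c(14, 7, 12), "gcs") # minimum: 7
#' worst_value_aggregate(c(80, 125, 61), "hr") # 125 scores 4 pts, worst
#' @export
worst_value_aggregate <- function(measurements, feature_name) {
  stopifnot(is.numeric(measurements))
  direction <- worseness_direction(feature_name) # errors if unregistered
  x <- measurements[!is.na(measurements)]
  if (length(x) == 0) return(NA_real_)
  if (direction == "min") return(min(x))
  pts <- saps_points(x, feature_name)
  candidates <- x[pts == max(pts)]
  if (length(candidates) == 1) return(candidates)
  mid <- normal_band_midpoint(feature_name)
  # farther from the normal-range midpoint = worse; ties beyond that are
  # value-identical in band terms, keep the smallest for determinism
  dist <- abs(candidates - mid)
  worst <- candidates[dist == max(dist)]
  min(worst)
}
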