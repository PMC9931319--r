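# Independent oracles used across tests. Deliberately naive implementations:
# correctness over speed, and no shared code paths with the package.

# All-pairs AUC: count positive-negative pairs, ties worth one half.
auc_brute_force <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Double-loop unbiased MMD^2 with a Gaussian kernel (paired form for m == n).
mmd2_double_loop <- function(x, y, bandwidth) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * bandwidth^2))
  m <- nrow(x); n <- nrow(y)
  sxx <- 0
  for (i in 1:m) for (j in 1:m) if (i != j) sxx <- sxx + k(x[i, ], x[j, ])
  syy <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) syy <- syy + k(y[i, ], y[j, ])
  if (m == n) {
    sxy <- 0
    for (i in 1:m) for (j in 1:m) if (i != j) sxy <- sxy + k(x[i, ], y[j, ])
    sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * (m - 1))
  } else {
    sxy <- 0
    for (i in 1:m) for (j in 1:n) sxy <- sxy + k(x[i, ], y[j, ])
    sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
  }
}

# SAPS II severity bands, re-encoded independently from Le Gall et al. (1993)
# for worst-value cross-checks: points(value) per feature.
saps_points_oracle <- function(value, feature) {
  switch(feature,
    hr = if (value < 40) 11 else if (value < 70) 2 else if (value < 120) 0
         else if (value < 160) 4 else 7,
    sysbp = if (value < 70) 13 else if (value < 100) 5
            else if (value < 200) 0 else 2,
    temp = if (value < 39) 0 else 3,
    bun = if (value < 28) 0 else if (value < 84) 6 else 10,
    wbc = if (value < 1) 12 else if (value < 20) 0 else 3,
    potassium = if (value < 3) 3 else if (value < 5) 0 else 3,
    sodium = if (value < 125) 5 else if (value < 145) 0 else 1,
    bicarbonate = if (value < 15) 6 else if (value < 20) 3 else 0,
    bilirubin = if (value < 4) 0 else if (value < 6) 4 else 9,
    stop("no oracle bands for ", feature)
  )
}

saps_normal_midpoint_oracle <- function(feature) {
  switch(feature,
    hr = 95, sysbp = 150, temp = 39, bun = 28, wbc = 10.5,
    potassium = 4, sodium = 135, bicarbonate = 20, bilirubin = 4,
    stop("no oracle midpoint for ", feature)
  )
}

worst_value_oracle <- function(values, feature) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  if (feature %in% c("gcs", "urineoutput", "pao2fio2")) return(min(values))
  pts <- vapply(values, saps_points_oracle, numeric(1), feature = feature)
  cand <- values[pts == max(pts)]
  mid <- saps_normal_midpoint_oracle(feature)
  cand <- cand[abs(cand - mid) == max(abs(cand - mid))]
  min(cand)
}

# Type-7 quantile by explicit order statistics (oracle for the aggregation).
quantile_type7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Small default-pattern cohort shared by several tests.
tiny_cohort <- function(stays = 150, seed = 42) {
  sample_cohort(default_scenario(stays_per_hospital = stays, seed = seed))
}
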