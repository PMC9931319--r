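#' Median-heuristic kernel bandwidth
#'
#' Median pairwise Euclidean distance over the pooled sample, the standard
#' bandwidth choice for Gaussian-kernel MMD two-sample tests. For pooled
#' samples above `max_rows` rows a fixed-seed subsample keeps the cost bounded.
#' Floored at a small epsilon so degenerate (all-identical) samples still give
#' a usable kernel.
#'
#' @param x,y Numeric matrices with the same number of columns.
#' @param max_rows Subsampling cap for the pooled sample.
#' @param eps Lower floor for the bandwidth.
#' @return A positive scalar bandwidth.
#' @export
median_heuristic_bandwidth <- function(x, y, max_rows = 1000L, eps = 1e-8) {
  pooled <- rbind(as.matrix(x), as.matrix(y))
  if (nrow(pooled) < 2) stop("pooled sample must have >= 2 rows", call. = FALSE)
  if (nrow(pooled) > max_rows) {
    set.seed(max_rows) # fixed internal seed: bandwidth is a deterministic map
    pooled <- pooled[sample(nrow(pooled), max_rows), , drop = FALSE]
  }
  d <- stats::dist(pooled)
  max(stats::median(d), eps)
}

squared_distance_matrix <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Unbiased squared maximum mean discrepancy
#'
#' U-statistic estimate of MMD^2 between two samples under a Gaussian kernel
#' `k(a, b) = exp(-||a - b||^2 / (2 * bandwidth^2))`: the off-diagonal means of
#' the within-sample kernel matrices minus twice the cross-sample mean. For
#' equal sample sizes the paired unbiased form is used (matched cross terms
#' excluded), which cancels exactly to 0 when the two samples are identical.
#'
#' @param x,y Numeric matrices (>= 2 rows each, same columns).
#' @param bandwidth Positive kernel bandwidth; defaults to the median
#'   heuristic.
#' @return A scalar; negative values are possible (unbiasedness).
#' @export
mmd2_unbiased <- function(x, y, bandwidth = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  m <- nrow(x)
  n <- nrow(y)
  if (m < 2 || n < 2) stop("each sample needs >= 2 rows", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- median_heuristic_bandwidth(x, y)
  stopifnot(bandwidth > 0)
  kxx <- exp(-squared_distance_matrix(x, x) / (2 * bandwidth^2))
  kyy <- exp(-squared_distance_matrix(y, y) / (2 * bandwidth^2))
  kxy <- exp(-squared_distance_matrix(x, y) / (2 * bandwidth^2))
  sxx <- (sum(kxx) - m) / (m * (m - 1))
  syy <- (sum(kyy) - n) / (n * (n - 1))
  cross <- if (m == n) {
    (sum(kxy) - sum(diag(kxy))) / (m * (m - 1))
  } else {
    mean(kxy)
  }
  sxx + syy - 2 * cross
}

#' Kernel two-sample permutation test
#'
#' Tests the null hypothesis that two samples come from the same distribution,
#' using an MMD^2 statistic and a permutation null: pooled rows are reassigned
#' to the two samples (sizes preserved) `B` times, and
#' `p = (1 + #{permuted >= observed}) / (B + 1)`. The same statistic
#' functional is evaluated on the observed assignment and every permuted one
#' (exchangeability makes the p-value exactly valid under the null); the
#' reported `mmd2` estimate is [mmd2_unbiased()]. The bandwidth is computed
#' once from the pooled sample and held fixed across permutations.
#'
#' @param x,y Numeric matrices.
#' @param B Number of permutations (>= 99).
#' @param bandwidth Kernel bandwidth; median heuristic by default.
#' @param level Significance level for the `reject` flag.
#' @param seed Integer seed for the permutations.
#' @return A `shift_result`: list with `mmd2`, `p_value`, `reject`,
#'   `bandwidth`, `n_permutations`.
#' @export
mmd_permutation_test <- function(x, y, B = 200L, bandwidth = NULL,
                                 level = 0.05, seed = 1L) {
  stopifnot(B >= 99)
  x <- as.matrix(x)
  y <- as.matrix(y)
  m <- nrow(x)
  n <- nrow(y)
  if (is.null(bandwidth)) bandwidth <- median_heuristic_bandwidth(x, y)
  pooled <- rbind(x, y)
  k <- exp(-squared_distance_matrix(pooled, pooled) / (2 * bandwidth^2))
  set.seed(seed)
  assign <- matrix(FALSE, m + n, B + 1L)
  assign[seq_len(m), 1] <- TRUE # observed assignment first
  for (b in seq_len(B) + 1L) assign[sample(m + n, m), b] <- TRUE
  stats_all <- mmd2_perm_stats(k, assign, m, n)
  p <- (1 + sum(stats_all[-1] >= stats_all[1])) / (B + 1)
  structure(
    list(mmd2 = mmd2_unbiased(x, y, bandwidth), p_value = p,
         reject = p < level, bandwidth = bandwidth, n_permutations = B,
         level = level),
    class = "shift_result"
  )
}

# Test statistic per label assignment, vectorized over the columns of
# `assign` via the pooled kernel matrix: off-diagonal within-sample means
# minus twice the full cross mean. Not the paired unbiased estimate, but the
# identical functional for observed and permuted assignments, which is all a
# permutation test requires.
mmd2_perm_stats <- function(k, assign, m, n) {
  zx <- assign * 1
  zy <- 1 - zx
  kzx <- k %*% zx
  sxx <- colSums(zx * kzx) - m # subtract the m unit diagonal terms
  syy <- colSums(zy * (k %*% zy)) - n
  sxy <- colSums(zy * kzx)
  sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "<shift_result> MMD^2 = %.6g, p = %.4g (%d permutations, bandwidth %.4g)%s\n",
    x$mmd2, x$p_value, x$n_permutations, x$bandwidth,
    if (x$reject) " *shift detected*" else ""
  ))
  invisible(x)
}

#' @rdname tidy.risk_model
#' @export
tidy.shift_result <- function(x, ...) {
  tibble::tibble(mmd2 = x$mmd2, p_value = x$p_value, reject = x$reject,
                 bandwidth = x$bandwidth, n_permutations = x$n_permutations)
}

#' Pairwise dataset-shift matrix across environments
#'
#' For every unordered pair of environments, draws `replicates` subsamples of
#' `n` rows from each side, runs the MMD^2 permutation test on the imputed,
#' pooled-standardized feature matrix, and averages the statistic, p-value and
#' rejection indicator. The outcome column is excluded from the tested features
#' by default. Only the lower triangle is emitted (the statistic is symmetric).
#'
#' @param cohort A cohort tibble.
#' @param environment_key Grouping key, see [assign_environment()].
#' @param n Rows per environment per replicate.
#' @param replicates Subsample replicates per pair.
#' @param B Permutations per test.
#' @param level Significance level.
#' @param include_outcome Include the mortality column among tested features.
#' @param seed Integer seed.
#' @return A `shift_matrix` tibble: `env_a`, `env_b`, `mean_mmd2`, `mean_p`,
#'   `reject_fraction`.
#' @export
pairwise_shift_matrix <- function(cohort, environment_key = "hospital",
                                  n = 500L, replicates = 10L, B = 200L,
                                  level = 0.05, include_outcome = FALSE,
                                  seed = 1L) {
  cohort <- assign_environment(cohort, environment_key)
  feats <- model_features()
  if (include_outcome) feats <- c(feats, "mortality")
  # pooled imputation + standardization so scale differences don't dominate
  pre <- fit_preprocessor(cohort, full = cohort, mode = "train_mean",
                          features = setdiff(feats, "mortality"))
  std <- transform_cohort(cohort, pre)
  envs <- sort(unique(std$env))
  sizes <- table(std$env)
  if (any(sizes < n)) {
    stop("environments smaller than n: ",
         paste(names(sizes)[sizes < n], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(envs, 2)
  seeds <- matrix(derive_seeds(seed, 3L * ncol(pairs) * replicates), ncol = 3)
  cell <- 0L
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[2, p] # lower triangle: env_a is the later environment
    b <- pairs[1, p]
    stats_rep <- matrix(NA_real_, replicates, 3)
    for (r in seq_len(replicates)) {
      cell <- cell + 1L
      xa <- feature_matrix(
        subsample_environment(std, a, n, seeds[cell, 1]), feats)
      xb <- feature_matrix(
        subsample_environment(std, b, n, seeds[cell, 2]), feats)
      res <- mmd_permutation_test(xa, xb, B = B, level = level,
                                  seed = seeds[cell, 3])
      stats_rep[r, ] <- c(res$mmd2, res$p_value, res$reject)
    }
    rows[[p]] <- tibble::tibble(
      env_a = a, env_b = b,
      mean_mmd2 = mean(stats_rep[, 1]),
      mean_p = mean(stats_rep[, 2]),
      reject_fraction = mean(stats_rep[, 3])
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shift_matrix", class(out))
  out
}
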