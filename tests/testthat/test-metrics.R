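test_that("AUC agrees with the all-pairs oracle, including ties", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_true(is.na(roc_auc(c(1, 1), c(0.2, 0.3))))
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(5:150, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2) # coarse grid forces ties
    expect_equal(roc_auc(labels, scores), auc_brute_force(labels, scores))
  }
})

test_that("calibration slope is 1 for self-generated outcomes and scales generatively", {
  set.seed(21)
  l <- rnorm(30000, -2.2, 1)
  y <- rbinom(30000, 1, plogis(l))
  expect_lt(abs(calibration_slope(y, plogis(l)) - 1), 0.05)
  # risks with doubled logits: true slope 0.5 by construction
  y2 <- rbinom(30000, 1, plogis(l))
  expect_lt(abs(calibration_slope(y2, plogis(2 * l)) - 0.5), 0.05)
  # an overconfident model shows slope < 1
  expect_lt(calibration_slope(y2, plogis(2 * l)), 1)
  # undefined cases
  expect_true(is.na(calibration_slope(rep(1, 10), runif(10))))
  expect_true(is.na(calibration_slope(rbinom(10, 1, 0.5), rep(0.3, 10))))
})

test_that("generalization gap is a signed test-minus-validation difference", {
  expect_equal(generalization_gap(0.86, 0.88), -0.02)
  expect_equal(generalization_gap(0.5, 0.5), 0)
  expect_lt(generalization_gap(0.7, 0.9), 0) # worse on test => negative
  expect_true(is.na(generalization_gap(NA_real_, 0.9)))
})

test_that("prevalence threshold is the test mortality rate", {
  expect_equal(prevalence_threshold(c(rep(1, 5), rep(0, 95))), 0.05)
  labels <- c(1, 0, 0, 1, 0, 0, 0, 1, 0, 0)
  expect_equal(prevalence_threshold(labels), sum(labels == 1) / 10)
  expect_equal(prevalence_threshold(rep(0, 4)), 0)
  expect_error(prevalence_threshold(numeric(0)), "labels")
})

test_that("FNR counts positives below threshold and is monotone in the threshold", {
  expect_equal(fnr_at_threshold(c(1, 1, 1), c(0.2, 0.6, 0.9), 0.5), 1 / 3)
  expect_equal(fnr_at_threshold(c(1, 0, 1), c(0.3, 0.2, 0.6), 0), 0)
  expect_equal(fnr_at_threshold(c(1, 0, 1), c(0.3, 0.2, 0.6), 0.99), 1)
  # risk equal to the threshold counts as predicted positive
  expect_equal(fnr_at_threshold(1, 0.5, 0.5), 0)
  expect_true(is.na(fnr_at_threshold(c(0, 0), c(0.1, 0.2), 0.5)))
  set.seed(22)
  labels <- rbinom(300, 1, 0.3)
  risks <- runif(300)
  fnrs <- vapply(seq(0, 1, 0.05), fnr_at_threshold, numeric(1),
                 labels = labels, risks = risks)
  expect_true(all(diff(fnrs) >= 0))
})

test_that("group disparity is an antisymmetric minority-minus-majority difference", {
  expect_equal(group_disparity(0.3, 0.2), 0.1)
  expect_equal(group_disparity(0.4, 0.4), 0)
  expect_equal(group_disparity(0.2, 0.3), -group_disparity(0.3, 0.2))
  expect_true(is.na(group_disparity(NA_real_, 0.3)))
})

test_that("percentage change uses an absolute-value denominator", {
  expect_equal(percentage_change(0.88, 0.86), 100 * (0.86 - 0.88) / 0.88)
  expect_lt(abs(percentage_change(0.88, 0.86) - (-2.27)), 0.01)
  expect_equal(percentage_change(0.5, 0.5), 0)
  expect_equal(percentage_change(-0.5, -0.25), 50)
  expect_true(is.na(percentage_change(0, 0.3)))
})

test_that("evaluate_predictions satisfies the disparity identities", {
  set.seed(23)
  n <- 4000
  race <- ifelse(rbinom(n, 1, 0.3) == 1, "minority", "majority")
  l <- rnorm(n, -2, 1)
  y <- rbinom(n, 1, plogis(l))
  m <- evaluate_predictions(y, plogis(l), race_group = race)
  expect_equal(m$disparity_fnr, m$fnr_minority - m$fnr_majority)
  expect_equal(m$disparity_cs, m$cs_minority - m$cs_majority)
  expect_equal(m$threshold, mean(y))
  # swapping group labels flips the disparity signs
  swapped <- ifelse(race == "minority", "majority", "minority")
  m2 <- evaluate_predictions(y, plogis(l), race_group = swapped)
  expect_equal(m2$disparity_fnr, -m$disparity_fnr)
  expect_equal(m2$disparity_cs, -m$disparity_cs, tolerance = 1e-8)
  # absent group: fairness metrics undefined
  m3 <- evaluate_predictions(y, plogis(l), race_group = rep("majority", n))
  expect_true(is.na(m3$disparity_fnr))
})

test_that("aggregation matches explicit order statistics and respects the diagonal flag", {
  vals <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  tm <- tibble::tibble(
    train_env = rep(c("a", "b", "c"), each = 3),
    test_env = rep(c("b", "c", "a"), each = 3),
    replicate = rep(1:3, 3),
    metric = "auc",
    value = vals
  )
  agg <- aggregate_transfer(tm)
  expect_equal(agg$median, quantile_type7_oracle(vals, 0.5))
  expect_equal(agg$q1, quantile_type7_oracle(vals, 0.25))
  expect_equal(agg$q3, quantile_type7_oracle(vals, 0.75))
  expect_true(all(agg$q1 <= agg$median & agg$median <= agg$q3))

  # constant metric collapses the quartiles
  tmc <- dplyr::mutate(tm, value = 0.8)
  aggc <- aggregate_transfer(tmc)
  expect_equal(aggc$median, 0.8)
  expect_equal(aggc$q1, aggc$q3)

  # diagonal exclusion only changes membership, not replicate values
  tmd <- dplyr::bind_rows(tm, tibble::tibble(
    train_env = "a", test_env = "a", replicate = 1:3,
    metric = "auc", value = c(100, 100, 100)
  ))
  off <- aggregate_transfer(tmd, off_diagonal_only = TRUE)
  expect_equal(off$median, agg$median)
  expect_equal(off$n, 9)

  # NA replicates are dropped with counts
  tmna <- dplyr::bind_rows(tm, tibble::tibble(
    train_env = "a", test_env = "b", replicate = 4,
    metric = "auc", value = NA_real_
  ))
  aggna <- aggregate_transfer(tmna)
  expect_equal(aggna$n_dropped, 1)
  expect_equal(aggna$median, agg$median)

  # signed and absolute disparity summaries are both reported
  tmd2 <- dplyr::mutate(tm, metric = "disparity_cs",
                        value = c(-3, -2, -1, 1, 2, 3, -2, 0, 2))
  agg2 <- aggregate_transfer(tmd2)
  expect_setequal(agg2$metric, c("disparity_cs", "abs_disparity_cs"))
  expect_equal(agg2$median[agg2$metric == "disparity_cs"], 0)
  expect_equal(agg2$median[agg2$metric == "abs_disparity_cs"], 2)
})

test_that("gap-shift correlation recovers a constructed monotone link", {
  set.seed(24)
  envs <- paste0("e", 1:6)
  pairs <- expand.grid(train_env = envs, test_env = envs,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$train_env != pairs$test_env, ]
  key <- paste(pmin(pairs$train_env, pairs$test_env),
               pmax(pairs$train_env, pairs$test_env))
  mmd <- setNames(runif(length(unique(key)), 0, 0.5), unique(key))
  gaps <- -2 * mmd[key] + rnorm(nrow(pairs), 0, 0.02)
  tm <- tibble::tibble(train_env = pairs$train_env, test_env = pairs$test_env,
                       replicate = 1L, metric = "gap_cs",
                       value = as.numeric(gaps))
  shifts <- tibble::tibble(
    env_a = pmax(pairs$train_env, pairs$test_env),
    env_b = pmin(pairs$train_env, pairs$test_env),
    mean_mmd2 = as.numeric(mmd[key])
  ) |> dplyr::distinct()
  out <- gap_shift_correlation(tm, shifts)
  expect_lt(out$correlation[out$gap_metric == "gap_cs"], -0.9)
  # jointly relabeling the environments leaves the correlation unchanged
  relabel <- setNames(paste0("x", 6:1), envs)
  tm2 <- dplyr::mutate(tm, train_env = relabel[train_env],
                       test_env = relabel[test_env])
  shifts2 <- dplyr::mutate(shifts,
                           env_a0 = relabel[env_a], env_b0 = relabel[env_b],
                           env_a = pmax(env_a0, env_b0),
                           env_b = pmin(env_a0, env_b0))
  out2 <- gap_shift_correlation(tm2, shifts2[, c("env_a", "env_b", "mean_mmd2")])
  expect_equal(out2$correlation, out$correlation, tolerance = 1e-12)
  # constant gaps have no defined correlation
  tmc <- dplyr::mutate(tm, value = 0.1)
  expect_true(is.na(gap_shift_correlation(tmc, shifts)$correlation))
})
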