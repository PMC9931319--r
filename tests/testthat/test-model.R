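test_that("zero-penalty limit matches the unpenalized maximum-likelihood fit", {
  set.seed(10)
  n <- 600
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rbinom(n, 1, plogis(x %*% c(0.8, -0.5, 0.2, 0) - 1))
  m <- fit_risk_model(x, y, strength = 1e-9)
  gl <- glm(y ~ x, family = binomial())
  expect_lt(max(abs(c(m$intercept, m$coefficients) - coef(gl))), 1e-4)
})

test_that("penalized fit matches an independent ridge-logistic solver", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  n <- 800
  x <- matrix(rnorm(n * 5), n)
  y <- rbinom(n, 1, plogis(x %*% c(1, -0.5, 0.3, 0, 0.8) - 1))
  strength <- 2
  m <- fit_risk_model(x, y, strength = strength)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = strength / n, standardize = FALSE,
                      thresh = 1e-14)
  expect_lt(max(abs(c(m$intercept, m$coefficients) -
                      as.numeric(glmnet::coef.glmnet(g)))), 1e-5)
})

test_that("the penalty keeps separable data finite and single-class data errors", {
  x <- matrix(c(-2, -1, 1, 2), 4, dimnames = list(NULL, "x1"))
  m <- fit_risk_model(x, c(0, 0, 1, 1), strength = 1)
  expect_true(is.finite(m$coefficients[["x1"]]))
  expect_error(fit_risk_model(x, c(1, 1, 1, 1)), "single class")
})

test_that("risk predictions equal the logistic linear predictor", {
  m <- structure(
    list(intercept = -1.5, coefficients = c(a = 0.4, b = -0.8),
         regularization_strength = 1, preprocessor = NULL),
    class = "risk_model"
  )
  x <- matrix(c(1, 0, -2, 0.5, 1, 3), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_risk(m, x),
               plogis(-1.5 + x[, 1] * 0.4 + x[, 2] * (-0.8)))
  # all-zero features give plogis(intercept)
  expect_equal(predict_risk(m, matrix(0, 1, 2)), plogis(-1.5))
  # monotone in a positive-coefficient feature
  lo <- predict_risk(m, matrix(c(0, 0), 1))
  hi <- predict_risk(m, matrix(c(2, 0), 1))
  expect_gt(hi, lo)
  expect_error(predict_risk(m, matrix(0, 1, 3)), "match")
})

test_that("tidy and glance expose the fitted model", {
  set.seed(12)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, 0.3)
  m <- fit_risk_model(x, y)
  td <- tidy(m)
  expect_equal(td$term, c("(intercept)", "a", "b"))
  expect_equal(td$estimate[1], m$intercept)
  gl <- glance(m)
  expect_equal(gl$n_features, 2)
  expect_equal(gl$n_train, 100)
})

test_that("environment subsampling is uniform, without replacement, and seeded", {
  cohort <- assign_environment(tiny_cohort(stays = 30), "hospital")
  draw <- subsample_environment(cohort, "h01", 30, seed = 5)
  expect_setequal(draw$stay_id, cohort$stay_id[cohort$hospital_id == "h01"])
  draw2 <- subsample_environment(cohort, "h02", 12, seed = 5)
  expect_equal(anyDuplicated(draw2$stay_id), 0)
  expect_identical(draw2, subsample_environment(cohort, "h02", 12, seed = 5))
  expect_error(subsample_environment(cohort, "h01", 31, seed = 1), "fewer")

  # inclusion frequency over repeated draws approximates n / N
  freq <- rowMeans(vapply(1:100, function(s) {
    cohort$stay_id[cohort$hospital_id == "h03"] %in%
      subsample_environment(cohort, "h03", 10, seed = s)$stay_id
  }, logical(30)))
  expect_true(all(abs(freq - 1 / 3) <= 3 * sqrt((1 / 3) * (2 / 3) / 100)))
})

test_that("train/validation split is disjoint, exhaustive, and sized by floor", {
  tbl <- tibble::tibble(id = 1:1631)
  parts <- split_train_validation(tbl, 0.9, seed = 9)
  expect_equal(nrow(parts$train), 1467)
  expect_equal(nrow(parts$validation), 164)
  expect_setequal(c(parts$train$id, parts$validation$id), tbl$id)
  expect_length(intersect(parts$train$id, parts$validation$id), 0)
  parts2 <- split_train_validation(tbl, 0.9, seed = 10)
  expect_false(setequal(parts$validation$id, parts2$validation$id))
})

test_that("transfer experiments are reproducible and produce the full grid", {
  cohort <- sample_cohort(default_scenario(n_hospitals = 3,
                                           stays_per_hospital = 250, seed = 2))
  plan <- experiment_plan("hospital", n_per_environment = 200,
                          n_subsamples = 3, seed = 77)
  tm <- run_transfer_experiment(cohort, plan)
  grid <- dplyr::distinct(tm[, c("train_env", "test_env")])
  expect_equal(nrow(grid), 9) # 3 x 3 ordered pairs, diagonal included
  expect_equal(max(tm$replicate), 3)
  tm2 <- run_transfer_experiment(cohort, plan)
  expect_equal(as.data.frame(tm), as.data.frame(tm2))
  # undersized environment rejected
  plan_big <- experiment_plan("hospital", n_per_environment = 500,
                              n_subsamples = 1)
  expect_error(run_transfer_experiment(cohort, plan_big), "smaller")
  # long CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_transfer_matrix(tm, path)
  back <- read_transfer_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(tm),
               ignore_attr = TRUE)
  expect_equal(back$value, tm$value)
})

test_that("region grouping pools hospitals into 4 environments", {
  cohort <- assign_environment(tiny_cohort(stays = 20), "region")
  expect_setequal(unique(cohort$env),
                  c("Northeast", "South", "Midwest", "West"))
  fine <- assign_environment(tiny_cohort(stays = 20), "region_beds_teaching")
  expect_true(all(grepl("/", fine$env)))
})
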