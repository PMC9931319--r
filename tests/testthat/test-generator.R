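test_that("sampled cohorts have the configured shape and are bit-reproducible", {
  cfg <- default_scenario(stays_per_hospital = 1631, seed = 7)
  cohort <- sample_cohort(cfg)
  expect_equal(nrow(cohort), 16310)
  expect_equal(length(unique(cohort$hospital_id)), 10)
  expect_equal(as.integer(table(cohort$hospital_id)), rep(1631L, 10))
  expect_identical(names(cohort), cohort_columns())
  expect_setequal(unique(cohort$region), c("Northeast", "South", "Midwest", "West"))
  expect_true(all(cohort$mortality %in% 0:1))
  expect_true(all(cohort$elective_surgery %in% 0:1))
  # bit-reproducible given the seed
  expect_identical(cohort, sample_cohort(cfg))
  # a different seed changes the draw
  cfg2 <- default_scenario(stays_per_hospital = 1631, seed = 8)
  expect_false(identical(cohort, sample_cohort(cfg2)))
})

test_that("zero shift coefficients give equal feature means across hospitals", {
  cohort <- sample_cohort(no_shift_scenario(seed = 13))
  for (f in c("temp", "gcs", "bun", "sysbp")) {
    sd_f <- sd(cohort[[f]])
    mu <- tapply(cohort[[f]], cohort$hospital_id, mean)
    # per-hospital mean of n = 1631 iid draws: 4 standard errors of slack
    expect_lt(max(abs(mu - mean(cohort[[f]]))), 4 * sd_f / sqrt(1631))
  }
  # minority fraction flat too
  mino <- tapply(cohort$race_group == "minority", cohort$hospital_id, mean)
  expect_lt(max(abs(mino - 0.2)), 4 * sqrt(0.2 * 0.8 / 1631))
})

test_that("default hospital mortality rates span the configured 4-9% band", {
  cohort <- sample_cohort(default_scenario(stays_per_hospital = 10000, seed = 21))
  prev <- as.numeric(tapply(cohort$mortality, cohort$hospital_id, mean))
  se <- sqrt(prev * (1 - prev) / 10000)
  expect_true(all(prev >= 0.040 - 2 * se))
  expect_true(all(prev <= 0.090 + 2 * se))
  expect_lt(min(prev), 0.05)  # band actually spanned, not collapsed
  expect_gt(max(prev), 0.075)
})

test_that("ground truth graph equals the non-zero coefficient set", {
  cfg <- default_scenario()
  g <- ground_truth_graph(cfg)
  spec <- cfg$feature_spec
  context_cols <- c(shift_hospital = "hospital_id", shift_region = "region",
                    shift_race = "race_group", shift_beds = "beds_band",
                    shift_teaching = "teaching")
  for (col in names(context_cols)) {
    expected <- spec$feature[spec[[col]] != 0]
    found <- g$edges$to[g$edges$from == context_cols[[col]] &
                          g$edges$to %in% spec$feature]
    expect_setequal(found, expected)
  }
  # mediation and outcome edges enumerated
  med <- cfg$mediation_edges
  for (r in seq_len(nrow(med))) {
    expect_true(any(g$edges$from == med$from[r] & g$edges$to == med$to[r]))
  }
  oc <- names(cfg$outcome_coefficients[cfg$outcome_coefficients != 0])
  expect_setequal(g$edges$from[g$edges$to == "mortality"],
                  c(oc, "race_group", "hospital_id"))
  expect_true(any(g$edges$from == "race_group" & g$edges$to == "sysbp"))
  # context indicators have no parents other than the hospital indicator
  expect_false(any(g$edges$to == "hospital_id"))
  # no-shift config: no context-to-feature edges at all
  g0 <- ground_truth_graph(no_shift_scenario())
  ctx <- c("hospital_id", "region", "beds_band", "teaching", "race_group")
  expect_equal(sum(g0$edges$from %in% ctx & g0$edges$to %in% spec$feature), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(
    cohort_config(n_hospitals = 1, stays_per_hospital = 10,
                  region_of_hospital = "South", beds_band = 1,
                  teaching = FALSE, base_mortality_logit = -3,
                  minority_proportion = 0.2,
                  mediation_edges = tibble::tibble(from = c("hr", "temp"),
                                                   to = c("temp", "hr"),
                                                   coef = c(0.3, 0.3))),
    "acyclic"
  )
  expect_error(
    cohort_config(n_hospitals = 2, stays_per_hospital = c(-5, 10),
                  region_of_hospital = c("South", "West"), beds_band = 1,
                  teaching = FALSE, base_mortality_logit = -3,
                  minority_proportion = 0.2),
    "stays_per_hospital"
  )
  expect_error(
    cohort_config(n_hospitals = 1, stays_per_hospital = 10,
                  region_of_hospital = "South", beds_band = 1,
                  teaching = FALSE, base_mortality_logit = -3,
                  minority_proportion = 1.4),
    "minority_proportion"
  )
})

test_that("missingness injection is MCAR at the configured rate and spares labels", {
  cfg <- recovery_scenario(stays_per_hospital = 10000, seed = 3)
  cfg$missingness_rate[] <- 0
  cfg$missingness_rate["bun"] <- 0.2
  cohort <- sample_cohort(cfg)
  with_na <- inject_missingness(cohort, cfg)
  frac <- mean(is.na(with_na$bun))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  # other columns untouched; labels and identifiers never missing
  expect_identical(with_na$temp, cohort$temp)
  expect_false(anyNA(with_na$mortality))
  expect_false(anyNA(with_na$stay_id))
  expect_false(anyNA(with_na$race_group))
  # zero rates leave the table unchanged; deterministic given the seed
  cfg0 <- cfg
  cfg0$missingness_rate[] <- 0
  expect_identical(inject_missingness(cohort, cfg0), cohort)
  expect_identical(with_na, inject_missingness(cohort, cfg))
  cfg$missingness_rate["bun"] <- 1
  expect_error(inject_missingness(cohort, cfg), "missingness_rate")
})

test_that("configs and cohorts round-trip through YAML and CSV", {
  cfg <- default_scenario(stays_per_hospital = 40)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  expect_equal(cfg2$base_mortality_logit, cfg$base_mortality_logit)
  expect_equal(cfg2$feature_spec$shift_race, cfg$feature_spec$shift_race)
  expect_identical(sample_cohort(cfg2), sample_cohort(cfg))

  cohort <- sample_cohort(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, csv)
  back <- read_cohort(csv)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})

test_that("synthetic measurement series aggregate back to the recorded worst value", {
  cohort <- tiny_cohort(stays = 30)
  for (f in c("gcs", "hr", "bilirubin")) {
    series <- sample_measurement_series(cohort, f, k = 4, seed = 5)
    recovered <- vapply(split(series$value, series$stay_id),
                        worst_value_aggregate, numeric(1), feature_name = f)
    expect_equal(unname(recovered[cohort$stay_id]), cohort[[f]])
  }
})
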