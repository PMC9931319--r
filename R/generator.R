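#' Configure a synthetic multi-hospital ICU cohort generator
#'
#' Builds the configuration for a structural causal model over a multi-hospital
#' ICU cohort: hospital/region/bed-size/teaching context, a binary race group
#' drawn per hospital, 12 physiological worst-value features plus age and an
#' elective-surgery indicator generated on a latent Gaussian scale with
#' context-driven mean shifts and feature-to-feature mediation, and a Bernoulli
#' in-hospital mortality outcome with optional race-modified feature effects.
#'
#' Hospital-level context effects enter features linearly through standardized
#' context scores (hospital index, region code, beds band, teaching flag), so
#' the induced dependences stay within the linear-Gaussian family that
#' Fisher-z conditional-independence tests assume.
#'
#' @param n_hospitals Number of hospitals.
#' @param stays_per_hospital Stays generated per hospital (scalar or vector).
#' @param region_of_hospital Character vector mapping each hospital to one of
#'   `"Northeast"`, `"South"`, `"Midwest"`, `"West"`.
#' @param beds_band Integer 1-3 bed-count band per hospital.
#' @param teaching Logical teaching-status flag per hospital.
#' @param base_mortality_logit Per-hospital intercept of the mortality model
#'   (log-odds scale).
#' @param minority_proportion Per-hospital probability a stay belongs to the
#'   minority race group, in `[0, 1]`.
#' @param feature_spec Tibble with one row per generated feature; see
#'   [default_feature_spec()].
#' @param mediation_edges Tibble with columns `from`, `to`, `coef`: direct
#'   feature-to-feature effects on the latent scale. Must be acyclic.
#' @param outcome_coefficients Named numeric vector of log-odds effects of each
#'   model feature (latent scale) on mortality.
#' @param outcome_race_interaction Named numeric vector of additional log-odds
#'   effects active for minority-group stays (race-dependent feature-outcome
#'   relationships). May be empty.
#' @param missingness_rate Named numeric vector of per-feature
#'   missing-completely-at-random rates in `[0, 1)`.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `cohort_config`.
#' @seealso [default_scenario()], [no_shift_scenario()], [sample_cohort()]
#' @export
cohort_config <- function(n_hospitals,
                          stays_per_hospital,
                          region_of_hospital,
                          beds_band,
                          teaching,
                          base_mortality_logit,
                          minority_proportion,
                          feature_spec = default_feature_spec(),
                          mediation_edges = default_mediation_edges(),
                          outcome_coefficients = default_outcome_coefficients(),
                          outcome_race_interaction = c(sysbp = 0.25, bun = -0.25),
                          missingness_rate = default_missingness_rate(),
                          seed = 1L) {
  recycle <- function(x) {
    if (length(x) == 1) rep(x, n_hospitals) else x
  }
  config <- structure(
    list(
      n_hospitals = as.integer(n_hospitals),
      stays_per_hospital = as.integer(recycle(stays_per_hospital)),
      region_of_hospital = recycle(region_of_hospital),
      beds_band = as.integer(recycle(beds_band)),
      teaching = as.logical(recycle(teaching)),
      base_mortality_logit = recycle(base_mortality_logit),
      minority_proportion = recycle(minority_proportion),
      feature_spec = feature_spec,
      mediation_edges = mediation_edges,
      outcome_coefficients = outcome_coefficients,
      outcome_race_interaction = outcome_race_interaction,
      missingness_rate = missingness_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(config)
  config
}

region_levels <- function() c("Northeast", "South", "Midwest", "West")

validate_cohort_config <- function(config) {
  with(config, {
    if (n_hospitals < 1) stop("n_hospitals must be >= 1", call. = FALSE)
    if (any(stays_per_hospital < 1)) {
      stop("stays_per_hospital must be >= 1", call. = FALSE)
    }
    for (field in c("stays_per_hospital", "region_of_hospital", "beds_band",
                    "teaching", "base_mortality_logit", "minority_proportion")) {
      if (length(config[[field]]) != n_hospitals) {
        stop(field, " must have length n_hospitals", call. = FALSE)
      }
    }
    if (!all(region_of_hospital %in% region_levels())) {
      stop("region_of_hospital values must be one of: ",
           paste(region_levels(), collapse = ", "), call. = FALSE)
    }
    if (any(minority_proportion < 0 | minority_proportion > 1)) {
      stop("minority_proportion must lie in [0, 1]", call. = FALSE)
    }
    if (any(missingness_rate < 0 | missingness_rate >= 1)) {
      stop("missingness_rate must lie in [0, 1)", call. = FALSE)
    }
    unknown <- setdiff(names(outcome_coefficients), feature_spec$feature)
    if (length(unknown) > 0) {
      stop("outcome_coefficients name features absent from feature_spec: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad_edge <- !(mediation_edges$from %in% feature_spec$feature) |
      !(mediation_edges$to %in% feature_spec$feature)
    if (any(bad_edge)) {
      stop("mediation_edges reference unknown features", call. = FALSE)
    }
    if (is.null(feature_topological_order(config))) {
      stop("mediation_edges must form an acyclic graph", call. = FALSE)
    }
  })
  invisible(config)
}

# Topological order of features under mediation_edges; NULL if cyclic.
feature_topological_order <- function(config) {
  feats <- config$feature_spec$feature
  edges <- config$mediation_edges
  indeg <- stats::setNames(rep(0L, length(feats)), feats)
  for (to in edges$to) indeg[to] <- indeg[to] + 1L
  order <- character(0)
  ready <- sort(names(indeg)[indeg == 0L])
  while (length(ready) > 0) {
    node <- ready[1]
    ready <- ready[-1]
    order <- c(order, node)
    kids <- edges$to[edges$from == node]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- sort(c(ready, k))
    }
  }
  if (length(order) != length(feats)) return(NULL)
  order
}

#' Default feature marginals and context shift coefficients
#'
#' One row per generated feature. Continuous features are Gaussian on a latent
#' standard scale and mapped to plausible clinical ranges by
#' `clinical_mean + clinical_sd * latent`; the elective-surgery indicator is
#' Bernoulli with a logit-scale specification. `shift_*` columns hold direct
#' context effects (per standardized context score, latent/logit scale). The
#' default pattern has the hospital indicator directly shifting age plus 3
#' vitals and 3 labs (and race composition, via per-hospital minority
#' proportions), and race directly shifting 4 vitals, 4 labs, and elective
#' surgery, with further region, bed-size and teaching effects on a few
#' features.
#'
#' @return A tibble.
#' @export
default_feature_spec <- function() {
  tibble::tribble(
    ~feature,           ~family,     ~clinical_mean, ~clinical_sd, ~base_logit, ~shift_hospital, ~shift_region, ~shift_race, ~shift_beds, ~shift_teaching,
    "age",              "normal",     63,             16,           NA,          0.35,            0,             0,           0,           0,
    "elective_surgery", "bernoulli",  NA,             NA,          -1.4,         0,               0,            -0.8,         0,           0,
    "hr",               "normal",     95,             22,           NA,          0,               0,             0.4,         0,           0.3,
    "sysbp",            "normal",    110,             28,           NA,          0,               0.35,         -0.5,         0,           0,
    "temp",             "normal",     37.4,           1.1,          NA,          0.4,             0,             0.3,         0,           0,
    "gcs",              "normal",     12,             3.5,          NA,         -0.45,            0,             0,           0,           0,
    "urineoutput",      "normal",   1500,            800,           NA,         -0.4,             0,             0,           0,           0,
    "pao2fio2",         "normal",    280,            110,           NA,          0,               0,            -0.4,         0.35,        0,
    "bun",              "normal",     28,             18,           NA,          0.4,             0,             0.35,        0,           0,
    "wbc",              "normal",     12,              5,           NA,          0.35,            0,             0,           0,           0,
    "potassium",        "normal",      4.2,            0.6,         NA,          0,               0,             0.3,         0,           0,
    "sodium",           "normal",    139,              5,           NA,          0.3,             0,             0,           0,           0,
    "bicarbonate",      "normal",     23,              4.5,         NA,          0,               0.4,          -0.35,        0,           0,
    "bilirubin",        "normal",      1.1,            1.4,         NA,          0,               0,             0.3,        -0.3,         0
  )
}

#' @rdname default_feature_spec
#' @export
default_mediation_edges <- function() {
  tibble::tribble(
    ~from,       ~to,           ~coef,
    "temp",      "hr",          0.4,   # fever raises heart rate
    "sysbp",     "urineoutput", 0.45,  # hypotension depresses urine output
    "gcs",       "pao2fio2",    0.35,  # depressed consciousness, ventilation
    "bun",       "potassium",   0.4,   # renal function drives potassium
    "bilirubin", "wbc",         0.3,
    "age",       "bun",         0.3
  )
}

#' @rdname default_feature_spec
#' @export
default_outcome_coefficients <- function() {
  c(
    age = 0.35, elective_surgery = -0.7,
    hr = 0.25, sysbp = -0.4, temp = 0.15, gcs = -0.8,
    urineoutput = -0.35, pao2fio2 = -0.3,
    bun = 0.4, wbc = 0.25, potassium = 0.2, sodium = 0.1,
    bicarbonate = -0.3, bilirubin = 0.2
  )
}

#' @rdname default_feature_spec
#' @export
default_missingness_rate <- function() {
  feats <- default_feature_spec()$feature
  rate <- stats::setNames(rep(0, length(feats)), feats)
  labs <- c("bun", "wbc", "potassium", "sodium", "bicarbonate", "bilirubin")
  vitals <- c("hr", "sysbp", "temp", "gcs", "urineoutput", "pao2fio2")
  rate[labs] <- 0.10
  rate[vitals] <- 0.05
  rate
}

#' Ready-made generator scenarios
#'
#' `default_scenario()` is the reference study condition: 10 hospitals in 4
#' regions with hospital-, region-, bed-size-, teaching- and race-mediated
#' feature shifts (see [default_feature_spec()]), per-hospital minority
#' proportions declining from 35% to 3%, and per-hospital mortality intercepts
#' calibrated so empirical mortality rates span roughly 4-9%.
#' `no_shift_scenario()` zeroes every context effect (identical hospitals) for
#' null-calibration experiments. `recovery_scenario()` is a single large
#' hospital without race-modified outcome effects, used for coefficient
#' recovery checks.
#'
#' @param n_hospitals,stays_per_hospital,seed Overridable size/seed settings.
#' @return A [cohort_config()].
#' @export
default_scenario <- function(n_hospitals = 10, stays_per_hospital = 1631,
                             seed = 20260101L) {
  h <- seq_len(n_hospitals)
  regions <- c("South", "Midwest", "Northeast", "West", "Midwest",
               "South", "West", "Northeast", "Midwest", "West")
  cohort_config(
    n_hospitals = n_hospitals,
    stays_per_hospital = stays_per_hospital,
    region_of_hospital = regions[((h - 1) %% 10) + 1],
    beds_band = c(2, 1, 3, 1, 3, 2, 1, 3, 2, 2)[((h - 1) %% 10) + 1],
    teaching = c(TRUE, FALSE, TRUE, FALSE, FALSE,
                 TRUE, FALSE, TRUE, TRUE, FALSE)[((h - 1) %% 10) + 1],
    # intercepts calibrated by Monte Carlo so per-hospital mortality rates
    # run linearly from ~4.2% to ~9.0% under the default shifts
    base_mortality_logit = c(-2.832, -2.915, -3.146, -3.088, -3.066,
                             -3.794, -3.752, -4.338, -4.301,
                             -4.272)[((h - 1) %% 10) + 1],
    minority_proportion = seq(0.35, 0.03, length.out = n_hospitals),
    seed = seed
  )
}

#' @rdname default_scenario
#' @export
no_shift_scenario <- function(n_hospitals = 10, stays_per_hospital = 1631,
                              seed = 20260101L) {
  spec <- default_feature_spec()
  spec$shift_hospital <- 0
  spec$shift_region <- 0
  spec$shift_race <- 0
  spec$shift_beds <- 0
  spec$shift_teaching <- 0
  h <- seq_len(n_hospitals)
  regions <- c("South", "Midwest", "Northeast", "West", "Midwest",
               "South", "West", "Northeast", "Midwest", "West")
  cohort_config(
    n_hospitals = n_hospitals,
    stays_per_hospital = stays_per_hospital,
    region_of_hospital = regions[((h - 1) %% 10) + 1],
    beds_band = c(2, 1, 3, 1, 3, 2, 1, 3, 2, 2)[((h - 1) %% 10) + 1],
    teaching = c(TRUE, FALSE, TRUE, FALSE, FALSE,
                 TRUE, FALSE, TRUE, TRUE, FALSE)[((h - 1) %% 10) + 1],
    base_mortality_logit = rep(-3.2, n_hospitals),
    minority_proportion = rep(0.2, n_hospitals),
    feature_spec = spec,
    outcome_race_interaction = numeric(0),
    seed = seed
  )
}

#' @rdname default_scenario
#' @export
recovery_scenario <- function(stays_per_hospital = 50000, seed = 20260101L) {
  cohort_config(
    n_hospitals = 1,
    stays_per_hospital = stays_per_hospital,
    region_of_hospital = "South",
    beds_band = 2,
    teaching = FALSE,
    base_mortality_logit = -2.6,
    minority_proportion = 0.2,
    outcome_race_interaction = numeric(0),
    seed = seed
  )
}

# Standardized context scores used as linear effect carriers.
context_scores <- function(config) {
  h <- seq_len(config$n_hospitals)
  hosp <- if (config$n_hospitals > 1) {
    (h - mean(h)) / stats::sd(h)
  } else {
    rep(0, 1)
  }
  region_code <- match(config$region_of_hospital, region_levels())
  region <- (region_code - 2.5) / stats::sd(1:4)
  beds <- (config$beds_band - 2) / sqrt(2 / 3)
  teach <- as.numeric(config$teaching) - 0.5
  list(hospital = hosp, region = region, beds = beds, teaching = teach,
       region_code = region_code)
}

#' Sample a synthetic multi-hospital ICU cohort
#'
#' Draws one row per ICU stay from the structural causal model described by a
#' [cohort_config()]: race group per hospital minority proportion, features in
#' topological order of the mediation DAG (Gaussian latents with context
#' shifts, affine-mapped to clinical scales; Bernoulli for elective surgery),
#' and mortality from a logistic model on the latent features. Bit-reproducible
#' given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns [cohort_columns()], one row per stay.
#' @examples
#' cohort <- sample_cohort(default_scenario(stays_per_hospital = 50))
#' dplyr::count(cohort, hospital_id)
#' @export
sample_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  scores <- context_scores(config)
  spec <- config$feature_spec
  n_per <- config$stays_per_hospital
  n <- sum(n_per)
  hosp_idx <- rep(seq_len(config$n_hospitals), times = n_per)

  race <- stats::rbinom(n, 1, config$minority_proportion[hosp_idx])

  order <- feature_topological_order(config)
  latent <- matrix(NA_real_, n, nrow(spec),
                   dimnames = list(NULL, spec$feature))
  for (feat in order) {
    row <- spec[spec$feature == feat, ]
    mu <- row$shift_hospital * scores$hospital[hosp_idx] +
      row$shift_region * scores$region[hosp_idx] +
      row$shift_race * race +
      row$shift_beds * scores$beds[hosp_idx] +
      row$shift_teaching * scores$teaching[hosp_idx]
    parents <- config$mediation_edges[config$mediation_edges$to == feat, ]
    if (nrow(parents) > 0) {
      mu <- mu + as.numeric(latent[, parents$from, drop = FALSE] %*% parents$coef)
    }
    if (row$family == "normal") {
      latent[, feat] <- mu + stats::rnorm(n)
    } else {
      latent[, feat] <- stats::rbinom(n, 1, stats::plogis(row$base_logit + mu))
    }
  }

  lp <- config$base_mortality_logit[hosp_idx]
  for (feat in names(config$outcome_coefficients)) {
    lp <- lp + config$outcome_coefficients[[feat]] * latent[, feat]
  }
  for (feat in names(config$outcome_race_interaction)) {
    lp <- lp + race * config$outcome_race_interaction[[feat]] * latent[, feat]
  }
  mortality <- stats::rbinom(n, 1, stats::plogis(lp))

  display <- tibble::as_tibble(latent)
  for (feat in spec$feature) {
    row <- spec[spec$feature == feat, ]
    if (row$family == "normal") {
      display[[feat]] <- row$clinical_mean + row$clinical_sd * display[[feat]]
    } else {
      display[[feat]] <- as.integer(display[[feat]])
    }
  }

  out <- tibble::tibble(
    stay_id = sprintf("s%07d", seq_len(n)),
    hospital_id = sprintf("h%02d", hosp_idx),
    region = config$region_of_hospital[hosp_idx],
    beds_band = config$beds_band[hosp_idx],
    teaching = config$teaching[hosp_idx],
    age = display$age,
    race_group = ifelse(race == 1, "minority", "majority"),
    elective_surgery = display$elective_surgery
  )
  for (feat in physiology_features()) out[[feat]] <- display[[feat]]
  out$mortality <- as.integer(mortality)
  out
}

#' Ground-truth causal graph of a generator configuration
#'
#' Returns the exact DAG implied by the non-zero coefficients of a
#' [cohort_config()]: context indicators (hospital, region, beds band,
#' teaching, race group) into features, deterministic hospital-to-attribute
#' edges, feature-to-feature mediation edges, and feature/race edges into
#' mortality. Used as the d-separation oracle when validating causal
#' discovery.
#'
#' @param config A [cohort_config()].
#' @return A `causal_dag` object: list with `nodes` and an `edges` tibble
#'   (`from`, `to`).
#' @export
ground_truth_graph <- function(config) {
  validate_cohort_config(config)
  spec <- config$feature_spec
  edges <- list()
  add <- function(from, to) tibble::tibble(from = from, to = to)
  # hospital determines its own attributes
  if (config$n_hospitals > 1) {
    if (length(unique(config$region_of_hospital)) > 1) {
      edges <- c(edges, list(add("hospital_id", "region")))
    }
    if (length(unique(config$beds_band)) > 1) {
      edges <- c(edges, list(add("hospital_id", "beds_band")))
    }
    if (length(unique(config$teaching)) > 1) {
      edges <- c(edges, list(add("hospital_id", "teaching")))
    }
    if (length(unique(config$minority_proportion)) > 1) {
      edges <- c(edges, list(add("hospital_id", "race_group")))
    }
  }
  context_cols <- c(shift_hospital = "hospital_id", shift_region = "region",
                    shift_race = "race_group", shift_beds = "beds_band",
                    shift_teaching = "teaching")
  for (col in names(context_cols)) {
    hit <- spec$feature[spec[[col]] != 0]
    # single-hospital configs have constant hospital-level scores
    if (col != "shift_race" && config$n_hospitals == 1) next
    if (col == "shift_region" &&
        length(unique(config$region_of_hospital)) == 1) next
    if (col == "shift_beds" && length(unique(config$beds_band)) == 1) next
    if (col == "shift_teaching" && length(unique(config$teaching)) == 1) next
    if (length(hit) > 0) edges <- c(edges, list(add(context_cols[[col]], hit)))
  }
  med <- config$mediation_edges[config$mediation_edges$coef != 0, ]
  if (nrow(med) > 0) edges <- c(edges, list(add(med$from, med$to)))
  oc <- config$outcome_coefficients[config$outcome_coefficients != 0]
  if (length(oc) > 0) edges <- c(edges, list(add(names(oc), "mortality")))
  if (config$n_hospitals > 1 &&
      length(unique(config$base_mortality_logit)) > 1) {
    edges <- c(edges, list(add("hospital_id", "mortality")))
  }
  if (length(config$outcome_race_interaction) > 0 &&
      any(config$outcome_race_interaction != 0)) {
    edges <- c(edges, list(add("race_group", "mortality")))
  }
  edge_tbl <- dplyr::distinct(dplyr::bind_rows(edges))
  nodes <- unique(c("hospital_id", "region", "beds_band", "teaching",
                    "race_group", spec$feature, "mortality"))
  causal_dag(nodes, edge_tbl)
}

#' Inject missing-completely-at-random values into a cohort
#'
#' Each feature value is independently set to `NA` with the per-feature rate in
#' `config$missingness_rate`. Identifiers, race group, and the mortality label
#' are never made missing. Deterministic given `config$seed`.
#'
#' @param cohort A cohort tibble from [sample_cohort()] (or the same schema).
#' @param config A [cohort_config()].
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, config) {
  rates <- config$missingness_rate
  if (any(rates < 0 | rates >= 1)) {
    stop("missingness_rate must lie in [0, 1)", call. = FALSE)
  }
  set.seed(config$seed + 104729L)
  for (feat in names(rates)) {
    if (rates[[feat]] == 0 || !feat %in% names(cohort)) next
    hit <- stats::runif(nrow(cohort)) < rates[[feat]]
    cohort[[feat]][hit] <- NA
  }
  cohort
}

#' Read and write cohort tables
#'
#' Cohorts are exchanged as CSV with the fixed header [cohort_columns()].
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` its path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[, cohort_columns()], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      stay_id = readr::col_character(),
      hospital_id = readr::col_character(),
      region = readr::col_character(),
      beds_band = readr::col_integer(),
      teaching = readr::col_logical(),
      race_group = readr::col_character(),
      elective_surgery = readr::col_integer(),
      mortality = readr::col_integer(),
      .default = readr::col_double()
    )
  )
}

#' Serialize a generator configuration to YAML
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `read_cohort_config()` returns a [cohort_config()];
#'   `write_cohort_config()` its path, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$feature_spec <- as.list(config$feature_spec)
  x$mediation_edges <- as.list(config$mediation_edges)
  x$outcome_coefficients <- as.list(config$outcome_coefficients)
  x$outcome_race_interaction <- as.list(config$outcome_race_interaction)
  x$missingness_rate <- as.list(config$missingness_rate)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort_config(
    n_hospitals = x$n_hospitals,
    stays_per_hospital = unlist(x$stays_per_hospital),
    region_of_hospital = unlist(x$region_of_hospital),
    beds_band = unlist(x$beds_band),
    teaching = unlist(x$teaching),
    base_mortality_logit = unlist(x$base_mortality_logit),
    minority_proportion = unlist(x$minority_proportion),
    feature_spec = tibble::as_tibble(lapply(x$feature_spec, unlist)),
    mediation_edges = tibble::as_tibble(lapply(x$mediation_edges, unlist)),
    outcome_coefficients = unlist(x$outcome_coefficients),
    outcome_race_interaction =
      if (length(x$outcome_race_interaction) == 0) numeric(0)
      else unlist(x$outcome_race_interaction),
    missingness_rate = unlist(x$missingness_rate),
    seed = x$seed
  )
}

#' Expand worst values into synthetic repeated measurements
#'
#' Companion to [worst_value_aggregate()]: for one physiological feature,
#' fabricates a measurement series per stay whose worst value (in the SAPS II
#' sense) equals the stay's recorded worst value, by adding measurements pulled
#' toward the feature's normal-range midpoint.
#'
#' @param cohort A cohort tibble.
#' @param feature_name One of [physiology_features()].
#' @param k Measurements per stay (>= 1).
#' @param seed Integer seed.
#' @return A long tibble: `stay_id`, `measurement_index`, `value`.
#' @export
sample_measurement_series <- function(cohort, feature_name, k = 3, seed = 1L) {
  stopifnot(k >= 1)
  set.seed(seed)
  worst <- cohort[[feature_name]]
  mid <- if (worseness_direction(feature_name) == "min") {
    max(worst, na.rm = TRUE) + stats::sd(worst, na.rm = TRUE)
  } else {
    normal_band_midpoint(feature_name)
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    if (is.na(worst[i])) return(NULL)
    # extra measurements sit strictly between the worst value and the
    # normal midpoint, so the recorded worst value stays the worst
    frac <- stats::runif(k - 1, 0.2, 0.9)
    values <- c(worst[i], worst[i] + frac * (mid - worst[i]))
    tibble::tibble(
      stay_id = cohort$stay_id[i],
      measurement_index = seq_len(k),
      value = values
    )
  })
  dplyr::bind_rows(rows)
}
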