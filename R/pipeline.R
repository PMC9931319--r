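#' Configure an end-to-end audit study
#'
#' @param generator A [cohort_config()], or `NULL` when `cohort_path` is given.
#' @param cohort_path CSV path of an existing cohort (alternative to
#'   `generator`).
#' @param plan An [experiment_plan()].
#' @param shift_n,shift_replicates,shift_B,shift_level Shift-test settings
#'   (subsample size, replicates per pair, permutations, significance level).
#' @param attribution_alpha,attribution_max_cond_size FCI settings.
#' @param indicators Context indicators for the attribution stage.
#' @param apply_missingness Inject the generator's missingness before analysis.
#' @param out_dir Output directory for the report bundle.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `study_config` object.
#' @export
study_config <- function(generator = NULL, cohort_path = NULL,
                         plan = experiment_plan(),
                         shift_n = 500L, shift_replicates = 10L,
                         shift_B = 200L, shift_level = 0.05,
                         attribution_alpha = 0.05,
                         attribution_max_cond_size = 3,
                         indicators = c("hospital_id", "region", "beds_band",
                                        "teaching", "race_group"),
                         apply_missingness = FALSE,
                         out_dir = "icushift-study", seed = 1L) {
  if (is.null(generator) && is.null(cohort_path)) {
    stop("supply a generator config or a cohort path", call. = FALSE)
  }
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    stop("cohort file does not exist: ", cohort_path, call. = FALSE)
  }
  structure(
    list(generator = generator, cohort_path = cohort_path, plan = plan,
         shift_n = shift_n, shift_replicates = shift_replicates,
         shift_B = shift_B, shift_level = shift_level,
         attribution_alpha = attribution_alpha,
         attribution_max_cond_size = attribution_max_cond_size,
         indicators = indicators, apply_missingness = apply_missingness,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Per-environment cohort summary
#'
#' Stay counts, mortality rate, minority fraction, and per-feature mean and
#' standard deviation for each environment under a grouping key.
#'
#' @param cohort A cohort tibble.
#' @param environment_key Grouping key, see [assign_environment()].
#' @return A tibble with one row per environment.
#' @export
summarize_environments <- function(cohort, environment_key = "hospital") {
  cohort <- assign_environment(cohort, environment_key)
  feats <- model_features()
  base <- cohort |>
    dplyr::group_by(env = .data$env) |>
    dplyr::summarise(
      n_stays = dplyr::n(),
      mortality_rate = mean(.data$mortality),
      minority_fraction = mean(.data$race_group == "minority"),
      .groups = "drop"
    )
  for (f in feats) {
    stats_f <- cohort |>
      dplyr::group_by(env = .data$env) |>
      dplyr::summarise(
        !!paste0(f, "_mean") := mean(.data[[f]], na.rm = TRUE),
        !!paste0(f, "_sd") := stats::sd(.data[[f]], na.rm = TRUE),
        .groups = "drop"
      )
    base <- dplyr::left_join(base, stats_f, by = "env")
  }
  base
}

#' Run the full audit study
#'
#' Orchestrates generate (or load) -> summarize -> transfer experiment ->
#' metric aggregation -> pairwise shift tests -> causal shift attribution ->
#' gap-versus-shift correlation, writing each artifact to `out_dir`:
#' `cohort_summary.csv`, `transfer_matrix.csv`, `aggregate_summary.csv`,
#' `shift_matrix.csv`, `pag_edges.csv`, `direct_shift_summary.csv`,
#' `gap_shift_correlation.csv`, and `run_log.txt`. Deterministic given
#' `config$seed`.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with all in-memory results.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  log_lines <- c(
    sprintf("icushift run, seed %d, %s", config$seed, format(Sys.time())),
    sprintf("R version: %s", R.version.string)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- stage("generate", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- seeds[1]
      cohort <- sample_cohort(gen)
      if (config$apply_missingness) cohort <- inject_missingness(cohort, gen)
      cohort
    } else {
      read_cohort(config$cohort_path)
    }
  })
  cohort <- stage("preprocess-filters", {
    cohort$age <- recode_age(cohort$age)
    apply_cohort_filters(cohort)
  })
  log_lines <- c(log_lines, sprintf("cohort: %d stays after filters",
                                    nrow(cohort)))

  env_summary <- stage("summarize",
                       summarize_environments(cohort,
                                              config$plan$environment_key))
  readr::write_csv(env_summary, file.path(config$out_dir, "cohort_summary.csv"))

  plan <- config$plan
  plan$seed <- seeds[2]
  transfer <- stage("transfer", run_transfer_experiment(cohort, plan))
  write_transfer_matrix(transfer, file.path(config$out_dir,
                                            "transfer_matrix.csv"))
  log_lines <- c(log_lines, attr(transfer, "log"))

  agg <- stage("aggregate", aggregate_transfer(transfer))
  readr::write_csv(agg, file.path(config$out_dir, "aggregate_summary.csv"))

  shifts <- stage("shift", pairwise_shift_matrix(
    cohort, environment_key = plan$environment_key,
    n = config$shift_n, replicates = config$shift_replicates,
    B = config$shift_B, level = config$shift_level, seed = seeds[3]
  ))
  readr::write_csv(shifts, file.path(config$out_dir, "shift_matrix.csv"))

  attribution <- stage("attribute", attribute_shifts(
    cohort, indicators = config$indicators,
    alpha = config$attribution_alpha,
    max_cond_size = config$attribution_max_cond_size
  ))
  write_pag(attribution$pag, file.path(config$out_dir, "pag_edges.csv"))
  readr::write_csv(attribution$summary,
                   file.path(config$out_dir, "direct_shift_summary.csv"))

  correlation <- stage("correlate", gap_shift_correlation(transfer, shifts))
  readr::write_csv(correlation,
                   file.path(config$out_dir, "gap_shift_correlation.csv"))

  log_lines <- c(log_lines,
                 sprintf("excluded replicates logged: %d",
                         length(attr(transfer, "log"))))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, environment_summary = env_summary,
                 transfer = transfer, aggregate = agg, shifts = shifts,
                 attribution = attribution, correlation = correlation))
}
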