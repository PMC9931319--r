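#' Pool environments into a joint causal inference dataset
#'
#' Builds the single pooled table on which causal discovery is run: the system
#' variables (model features and optionally the outcome) plus numerically
#' encoded context indicator columns. Hospitals are integer-coded in
#' identifier order, regions in the fixed `Northeast < South < Midwest < West`
#' order, beds band and teaching as their ordinal/flag codes, and race as a
#' minority indicator. Race is included as an indicator alongside the
#' environment attributes so race-mediated shifts are discoverable.
#'
#' @param cohort A cohort tibble.
#' @param indicators Context indicator columns to encode.
#' @param include_outcome Include the mortality column as a system variable.
#' @return A numeric tibble: indicator codes + system variables.
#' @export
build_jci_dataset <- function(cohort,
                              indicators = c("hospital_id", "region",
                                             "beds_band", "teaching",
                                             "race_group"),
                              include_outcome = TRUE) {
  missing_cols <- setdiff(indicators, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks indicator columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(.rows = nrow(cohort))
  for (ind in indicators) {
    out[[ind]] <- switch(ind,
      hospital_id = as.numeric(factor(cohort$hospital_id,
                                      levels = sort(unique(cohort$hospital_id)))),
      region = as.numeric(match(cohort$region, region_levels())),
      beds_band = as.numeric(cohort$beds_band),
      teaching = as.numeric(cohort$teaching),
      race_group = as.numeric(cohort$race_group == "minority"),
      as.numeric(cohort[[ind]])
    )
  }
  for (f in model_features()) out[[f]] <- as.numeric(cohort[[f]])
  if (include_outcome && "mortality" %in% names(cohort)) {
    out$mortality <- as.numeric(cohort$mortality)
  }
  out
}

#' JCI background knowledge
#'
#' Encodes the joint-causal-inference assumptions for [fci()]: context
#' indicators are exogenous (no incoming arrowheads) and mutually non-adjacent,
#' except for declared deterministic hospital-attribute relations
#' (hospital to region/beds/teaching) and the hospital-to-race composition
#' edge, which are kept and oriented away from the hospital indicator. Every
#' surviving context-system edge is oriented context to system.
#'
#' @param nodes All variable names of the pooled dataset.
#' @param context The environment context indicators.
#' @param race Name of the race indicator (kept adjacent to the environment
#'   contexts, itself exogenous with respect to the system variables), or
#'   `NULL` if race is not an indicator.
#' @param declared_edges Tibble (`from`, `to`) of permitted context-context
#'   edges; defaults to hospital into its attributes and race.
#' @return An [fci_knowledge()] object.
#' @export
jci_knowledge <- function(nodes,
                          context = c("hospital_id", "region", "beds_band",
                                      "teaching"),
                          race = "race_group",
                          declared_edges = NULL) {
  context <- intersect(context, nodes)
  race <- intersect(race, nodes)
  all_context <- c(context, race)
  if (is.null(declared_edges) && "hospital_id" %in% context) {
    declared_edges <- tibble::tibble(
      from = "hospital_id",
      to = intersect(c("region", "beds_band", "teaching", race), nodes)
    )
    declared_edges <- declared_edges[declared_edges$to != "hospital_id", ]
  }
  # context pairs not declared are forbidden adjacencies
  forbidden <- NULL
  if (length(all_context) > 1) {
    pairs <- utils::combn(all_context, 2)
    keep <- vapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      declared <- !is.null(declared_edges) &&
        any((declared_edges$from == a & declared_edges$to == b) |
              (declared_edges$from == b & declared_edges$to == a))
      !declared
    }, logical(1))
    if (any(keep)) {
      forbidden <- tibble::tibble(a = pairs[1, keep], b = pairs[2, keep])
    }
  }
  # orientations: declared context-context edges, plus context -> system
  system_nodes <- setdiff(nodes, all_context)
  oriented <- dplyr::bind_rows(
    declared_edges,
    tidyr::expand_grid(from = all_context, to = system_nodes)
  )
  fci_knowledge(nodes, forbidden_adjacency = forbidden,
                oriented_edges = oriented, no_incoming = all_context)
}

#' Attribute dataset shifts to directly affected variables
#'
#' Convenience wrapper for the shift-attribution analysis: pools the cohort
#' with [build_jci_dataset()], runs [fci()] under [jci_knowledge()], and
#' summarizes which variables are adjacent to each context indicator.
#'
#' @param cohort A cohort tibble.
#' @param indicators Context indicator columns.
#' @param alpha,max_cond_size Passed to [fci()].
#' @param include_outcome Include mortality as a system variable.
#' @return A list: `pag`, `summary` (a [direct_shift_summary()] tibble).
#' @export
attribute_shifts <- function(cohort,
                             indicators = c("hospital_id", "region",
                                            "beds_band", "teaching",
                                            "race_group"),
                             alpha = 0.05, max_cond_size = 3,
                             include_outcome = TRUE) {
  pooled <- build_jci_dataset(cohort, indicators, include_outcome)
  knowledge <- jci_knowledge(names(pooled),
                             context = setdiff(indicators, "race_group"),
                             race = intersect("race_group", indicators))
  pag <- fci(pooled, alpha = alpha, max_cond_size = max_cond_size,
             knowledge = knowledge)
  list(pag = pag, summary = direct_shift_summary(pag, indicators))
}

#' Variables directly shifted by each context indicator
#'
#' For each context indicator, the set of variables adjacent to it in the PAG
#' (any endpoint marks). Environment indicators other than the one in question
#' are excluded from its set, so the race indicator can appear in the hospital
#' row (hospitals shift race composition) while hospital/region/beds/teaching
#' never appear as "shifted variables" of one another.
#'
#' @param pag A `pag` from [fci()].
#' @param indicators Context indicator names present in the PAG.
#' @return A tibble: `indicator`, `variable`, one row per direct adjacency.
#' @export
direct_shift_summary <- function(pag,
                                 indicators = c("hospital_id", "region",
                                                "beds_band", "teaching",
                                                "race_group")) {
  missing_ind <- setdiff(indicators, pag$nodes)
  if (length(missing_ind) > 0) {
    stop("indicators not in the PAG: ",
         paste(missing_ind, collapse = ", "), call. = FALSE)
  }
  env_indicators <- setdiff(indicators, "race_group")
  rows <- lapply(indicators, function(ind) {
    adj <- pag_adjacencies(pag, ind)
    adj <- setdiff(adj, setdiff(env_indicators, ind))
    if (ind != "race_group") adj <- setdiff(adj, ind)
    if (length(adj) == 0) return(NULL)
    tibble::tibble(indicator = ind, variable = adj)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(indicator = character(0), variable = character(0))
  }
  class(out) <- c("direct_shift_summary", class(out))
  out
}

#' Binary indicator-by-variable matrix of a direct-shift summary
#'
#' @param summary A [direct_shift_summary()] tibble.
#' @param variables Column order (defaults to the variables present).
#' @return A 0/1 matrix, indicators as rows.
#' @export
shift_summary_matrix <- function(summary, variables = NULL) {
  if (is.null(variables)) variables <- sort(unique(summary$variable))
  indicators <- unique(summary$indicator)
  m <- matrix(0L, length(indicators), length(variables),
              dimnames = list(indicators, variables))
  for (r in seq_len(nrow(summary))) {
    if (summary$variable[r] %in% variables) {
      m[summary$indicator[r], summary$variable[r]] <- 1L
    }
  }
  m
}

#' Precision and recall of discovered direct shifts against a ground truth DAG
#'
#' Compares the (indicator, variable) adjacencies of a [direct_shift_summary()]
#' with the context-to-variable edges of the generator's
#' [ground_truth_graph()].
#'
#' @param summary A [direct_shift_summary()].
#' @param truth A [causal_dag()] from [ground_truth_graph()].
#' @param indicators Context indicators scored.
#' @param exclude_outcome Drop `mortality` from both sides (the outcome is a
#'   system variable, not a shifted feature).
#' @return A one-row tibble: `precision`, `recall`, `n_true`, `n_found`.
#' @export
score_shift_recovery <- function(summary, truth,
                                 indicators = c("hospital_id", "region",
                                                "beds_band", "teaching",
                                                "race_group"),
                                 exclude_outcome = TRUE) {
  truth_edges <- truth$edges[truth$edges$from %in% indicators, ]
  env <- setdiff(indicators, "race_group")
  truth_edges <- truth_edges[!(truth_edges$to %in% env), ]
  if (exclude_outcome) {
    truth_edges <- truth_edges[truth_edges$to != "mortality", ]
    summary <- summary[summary$variable != "mortality", ]
  }
  truth_keys <- paste(truth_edges$from, truth_edges$to)
  found_keys <- paste(summary$indicator, summary$variable)
  tp <- length(intersect(found_keys, truth_keys))
  tibble::tibble(
    precision = if (length(found_keys) == 0) NA_real_ else tp / length(found_keys),
    recall = if (length(truth_keys) == 0) NA_real_ else tp / length(truth_keys),
    n_true = length(truth_keys),
    n_found = length(found_keys)
  )
}
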