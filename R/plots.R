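#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a transfer experiment metric
#'
#' Train-by-test environment heatmap of the per-cell mean of one metric,
#' mirroring the usual presentation of cross-environment validation results.
#'
#' @param object A `transfer_matrix`.
#' @param metric Metric to display (e.g. `"auc"`, `"cs"`, `"gap_auc"`,
#'   `"disparity_fnr"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transfer_matrix <- function(object, metric = "auc", ...) {
  cells <- object |>
    dplyr::filter(.data$metric == !!metric) |>
    dplyr::group_by(.data$train_env, .data$test_env) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$test_env, y = .data$train_env,
                                      fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = "test environment", y = "train environment",
                  title = paste("Cross-environment", metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of pairwise dataset shift
#'
#' Lower-triangular heatmap of the mean MMD^2 (or mean p-value / rejection
#' fraction) between environment pairs.
#'
#' @param object A `shift_matrix` from [pairwise_shift_matrix()].
#' @param statistic One of `"mean_mmd2"`, `"mean_p"`, `"reject_fraction"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_matrix <- function(object, statistic = "mean_mmd2", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$env_b, y = .data$env_a,
                                       fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = statistic) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise dataset shift") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tile plot of directly shifted variables per context indicator
#'
#' @param object A [direct_shift_summary()] tibble.
#' @param variables Variable order on the x axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.direct_shift_summary <- function(object, variables = NULL, ...) {
  if (is.null(variables)) variables <- sort(unique(object$variable))
  grid <- tidyr::expand_grid(indicator = unique(object$indicator),
                             variable = variables)
  grid$shifted <- paste(grid$indicator, grid$variable) %in%
    paste(object$indicator, object$variable)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$variable, y = .data$indicator,
                                     fill = .data$shifted)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "white"),
                               name = "direct shift") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Variables directly shifted by each indicator") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname tidy.risk_model
#' @export
glance.transfer_matrix <- function(x, ...) {
  plan <- attr(x, "plan")
  tibble::tibble(
    n_environments = length(unique(c(x$train_env, x$test_env))),
    n_subsamples = if (!is.null(plan)) plan$n_subsamples else max(x$replicate),
    n_per_environment = if (!is.null(plan)) plan$n_per_environment else NA_integer_,
    n_excluded = length(attr(x, "log"))
  )
}

#' @rdname tidy.risk_model
#' @export
tidy.pag <- function(x, ...) {
  pag_edges(x)
}
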