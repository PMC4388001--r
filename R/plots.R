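#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-generation trajectories
#'
#' Replicate-mean trajectories of a metric against generation, one line per
#' selection matrix, faceted by scenario, with a +/- 1 SE ribbon when
#' summaries are available.
#'
#' @param x A `scenario_grid_result`, its `summary` tibble, or a raw
#'   metrics tibble from [run_replicate()].
#' @param metric Metric column to plot, e.g. `"delta_tbv"`,
#'   `"log_ratio_f_G"`, `"mean_f_A"`, `"heterozygosity"`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(x, metric = "delta_tbv") {
  if (inherits(x, "scenario_grid_result")) x <- x$summary
  if ("metric" %in% names(x)) {
    d <- dplyr::filter(x, .data$metric == !!metric)
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$mean,
                                         colour = .data$selection_matrix)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$mean - .data$se,
                     ymax = .data$mean + .data$se,
                     fill = .data$selection_matrix),
        alpha = 0.2, colour = NA) +
      ggplot2::geom_line()
  } else {
    d <- dplyr::group_by(x, .data$scenario, .data$selection_matrix,
                         .data$generation) |>
      dplyr::summarise(mean = mean(.data[[metric]]), .groups = "drop")
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$mean,
                                         colour = .data$selection_matrix)) +
      ggplot2::geom_line()
  }
  p +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "generation", y = metric,
                  colour = "selection on", fill = "selection on") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectories
#' @param object A metrics tibble (class `coansel_metrics`).
#' @param ... Passed on to [plot_trajectories()].
#' @export
autoplot.coansel_metrics <- function(object, ...) {
  plot_trajectories(object, ...)
}

#' Plot coancestry histograms
#'
#' Faceted histograms of the pairwise coancestries per matrix kind, each
#' annotated with the variance of its distribution.
#'
#' @param x A `coancestry_histograms` object.
#' @return A ggplot object.
#' @export
plot_coancestry_histograms <- function(x) {
  lab <- dplyr::mutate(x$variances,
                       label = paste0("var = ", signif(.data$var_f, 3)))
  ggplot2::ggplot(x$histogram,
                  ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "pairwise coancestry f", y = "count") +
    ggplot2::theme_minimal()
}
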