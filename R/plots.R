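#' Plot a simulation run
#'
#' Monthly population-size trajectory, with the perturbation window shaded
#' when the scenario is not the baseline.
#'
#' @param object A `"stress_run"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stress_run
#' @export
autoplot.stress_run <- function(object, ...) {
  p <- ggplot2::ggplot(object$monthly,
                       ggplot2::aes(x = .data$month / 12,
                                    y = .data$pop_size)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "population size",
                  title = sprintf("s_mean = %g, %s", object$cfg$s_mean,
                                  scenario_label(object$scenario))) +
    ggplot2::theme_minimal()
  sc <- object$scenario
  if (sc$kind != "baseline") {
    p <- p + ggplot2::annotate(
      "rect", xmin = sc$start_year, xmax = sc$start_year + sc$duration_years,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}

#' Plot a grid result
#'
#' Yearly mean population-size trajectories, coloured by population-mean
#' stress and facetted by scenario — the stratification view of the
#' experiment grid.
#'
#' @param object A `"stress_grid"` run with `keep_yearly = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stress_grid
#' @export
autoplot.stress_grid <- function(object, ...) {
  if (is.null(object$yearly)) abort("grid was run without yearly summaries")
  ggplot2::ggplot(object$yearly,
                  ggplot2::aes(x = .data$year, y = .data$mean_pop_size,
                               colour = .data$s_mean,
                               group = .data$s_mean)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::scale_colour_viridis_c(name = "mean stress") +
    ggplot2::labs(x = "year", y = "mean population size") +
    ggplot2::theme_minimal()
}

#' Plot final size against population-mean stress
#'
#' The stratification curve: mean final population size (log scale) by
#' mean stress level, optionally with the three-group segmentation marked.
#'
#' @param grid A `"stress_grid"`.
#' @param scenario Scenario label to plot (default `"baseline"`).
#' @param groups Optional result of [classify_groups()]; group boundaries
#'   are drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_stratification <- function(grid, scenario = "baseline", groups = NULL) {
  cells <- dplyr::filter(grid$cells, .data$scenario == !!scenario)
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$s_mean,
                                           y = .data$mean_final_size)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "population-mean stress",
                  y = "mean final population size") +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    cuts <- attr(groups, "cuts")
    p <- p + ggplot2::geom_vline(xintercept = c(mean(cuts$low),
                                                mean(cuts$high)),
                                 linetype = "dashed")
  }
  p
}
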