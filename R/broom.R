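#' Tidy a simulation run
#'
#' One row per simulated year: population size at the peak month, breeder
#' counts and breeder condition/age means (see [yearly_summaries()]).
#'
#' @param x A `"stress_run"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stress_run
#' @export
tidy.stress_run <- function(x, ...) yearly_summaries(x)

#' One-row summary of a simulation run
#'
#' @param x A `"stress_run"`.
#' @param ... Unused.
#' @return A tibble with `s_mean`, `scenario`, `sim_years`, `final_size`
#'   (mean over the last year), `extinct`, `extinction_month`,
#'   `total_births` and `seed`.
#' @method glance stress_run
#' @export
glance.stress_run <- function(x, ...) {
  tibble::tibble(
    s_mean = x$cfg$s_mean,
    scenario = scenario_label(x$scenario),
    sim_years = x$cfg$sim_years,
    final_size = final_size(x),
    extinct = x$extinct,
    extinction_month = x$extinction_month,
    total_births = sum(x$births$births),
    seed = x$seed)
}

#' Tidy a grid result
#'
#' The per-cell aggregate table: one row per (s_mean, scenario) with mean
#' and SD of final size, extinction fraction and convergence diagnostics.
#'
#' @param x A `"stress_grid"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stress_grid
#' @export
tidy.stress_grid <- function(x, ...) x$cells

#' One-row summary of a grid result
#'
#' @param x A `"stress_grid"`.
#' @param ... Unused.
#' @return A tibble with the grid dimensions and overall convergence.
#' @method glance stress_grid
#' @export
glance.stress_grid <- function(x, ...) {
  tibble::tibble(
    n_s_mean = length(x$grid$s_mean_values),
    n_scenarios = length(x$grid$scenarios),
    replicates = x$grid$replicates,
    n_cells = nrow(x$cells),
    frac_converged = mean(x$cells$converged, na.rm = TRUE),
    base_seed = x$grid$base_seed)
}
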