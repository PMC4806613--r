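#' Model configuration
#'
#' Builds the full set of constants driving the simulator: the seasonal
#' energy cycle, the trait distributions individuals are drawn from, the
#' two-threshold stress-energy compensation parameters, the reproduction
#' rules and the run dimensions. All values live on abstract scales that are
#' meaningful only relative to one another: stress impact on 0--50, physical
#' condition on 0--100, energy in arbitrary units per month.
#'
#' @param ... Named overrides of the defaults listed below. Unknown names
#'   are an error.
#'
#' @details
#' Energy environment:
#' \describe{
#'   \item{env_mean}{Mean monthly energy available in the environment
#'     (energy/month, default 1500). Sets the energetic ceiling and hence
#'     the quasi-carrying-capacity.}
#'   \item{env_amplitude}{Half-range of the seasonal triangular cycle
#'     (default 50). Ignored when `seasonal = FALSE`.}
#'   \item{peak_month}{Calendar month (0--11) at which energy peaks and
#'     reproduction occurs (default 5).}
#'   \item{seasonal}{If `FALSE`, energy is constant at `env_mean`
#'     (default `TRUE`).}
#'   \item{share_cap}{Resource saturation point: the per-capita share
#'     `env/P` enters foraging capped at this value (default 10).}
#' }
#' Stress distribution:
#' \describe{
#'   \item{s_mean, s_sd}{Population mean and SD of individual stress impact
#'     (defaults 25 and 15), truncated to `[s_lo, s_hi]` = `[0, 50]`.}
#'   \item{truncation}{`"clamp"` (default) clamps out-of-range normal draws
#'     to the bounds, so probability mass accumulates at 0 and 50;
#'     `"redraw"` rejection-samples instead.}
#' }
#' Stress energetics (see [net_stress_energy()]):
#' \describe{
#'   \item{threshold_A, threshold_B}{Compensation thresholds (defaults 15
#'     and 35): below A coping saves more energy than the stressor costs,
#'     between A and B the two cancel exactly, above B needs run away.}
#'   \item{benefit_slope, overload_slope}{Net energy per stress unit below A
#'     and above B (defaults 0.26 and 1.0; overload must exceed benefit).}
#'   \item{stress_forage_coeff}{Fractional loss of foraging effectiveness at
#'     maximal stress (default 1): gain is scaled by
#'     `1 - coeff * S / s_hi`.}
#' }
#' Individual traits:
#' \describe{
#'   \item{need_mean, need_sd}{Baseline energy requirement per month
#'     (defaults 6 and 1.5), truncated positive.}
#'   \item{rank_levels, rank_weight_lo, rank_weight_hi}{Foraging ranks are
#'     uniform on `1:rank_levels` (ties allowed) and map linearly onto
#'     multiplicative weights `[lo, hi]` (defaults 10, 0.3, 1.05).}
#'   \item{cond_birth_mean, cond_birth_sd, cond_max}{Condition at birth
#'     (defaults 55 and 30 on a 0--100 range) and the hard cap (100).}
#'   \item{maxage_mean_months, maxage_sd_months}{Maximal age drawn once at
#'     birth (defaults 120 and 24 months).}
#' }
#' Reproduction:
#' \describe{
#'   \item{repro_floor}{Minimum condition to breed (default 30).}
#'   \item{repro_exempt}{Condition above which the must-have-increased rule
#'     is waived (default 90).}
#'   \item{repro_cost_cap}{Maximum condition cost of breeding (default 20);
#'     the cost charged is `min(cap, condition - repro_floor)` under the
#'     default `cost_rule = "floor"`, or `min(cap, condition / 2)` under
#'     `"half"`.}
#' }
#' Run dimensions: `init_pop_size` (default 200), `sim_years` (default 25),
#' `seed` (default 1). `cap_mode` selects how the resource saturation enters
#' foraging: `"ratio"` (default) caps the per-capita share at `share_cap`;
#' `"scaled"` multiplies the share by `share_cap` before capping at the
#' full environmental supply, an alternative reading of the saturation rule.
#'
#' @return A named list of class `"stress_config"`.
#' @examples
#' cfg <- model_config(s_mean = 10, sim_years = 5)
#' cfg$threshold_A
#' @seealso [scenario_spec()], [grid_spec()], [read_config()]
#' @export
model_config <- function(...) {
  cfg <- config_defaults()
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == ""))) {
    abort("all arguments to model_config() must be named")
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, dots)
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    env_mean = 1500,
    env_amplitude = 50,
    peak_month = 5L,
    seasonal = TRUE,
    share_cap = 10,
    s_mean = 25,
    s_sd = 15,
    s_lo = 0,
    s_hi = 50,
    truncation = "clamp",
    threshold_A = 15,
    threshold_B = 35,
    benefit_slope = 0.26,
    overload_slope = 1.0,
    stress_forage_coeff = 1.0,
    need_mean = 6,
    need_sd = 1.5,
    rank_levels = 10L,
    rank_weight_lo = 0.3,
    rank_weight_hi = 1.05,
    cond_birth_mean = 55,
    cond_birth_sd = 30,
    cond_max = 100,
    repro_floor = 30,
    repro_exempt = 90,
    repro_cost_cap = 20,
    cost_rule = "floor",
    maxage_mean_months = 120L,
    maxage_sd_months = 24L,
    init_pop_size = 200L,
    sim_years = 25L,
    seed = 1L,
    cap_mode = "ratio"
  )
}

validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, keys) if (!isTRUE(ok)) bad <<- c(bad, keys)
  chk(is.numeric(cfg$env_mean) && cfg$env_mean > 0, "env_mean")
  chk(is.numeric(cfg$env_amplitude) && cfg$env_amplitude >= 0, "env_amplitude")
  chk(cfg$peak_month %in% 0:11, "peak_month")
  chk(is.logical(cfg$seasonal), "seasonal")
  chk(cfg$share_cap > 0, "share_cap")
  chk(cfg$s_lo < cfg$s_hi, c("s_lo", "s_hi"))
  chk(cfg$s_mean >= cfg$s_lo && cfg$s_mean <= cfg$s_hi, "s_mean")
  chk(cfg$s_sd >= 0, "s_sd")
  chk(cfg$truncation %in% c("clamp", "redraw"), "truncation")
  chk(cfg$threshold_A >= cfg$s_lo && cfg$threshold_A <= cfg$threshold_B,
      c("threshold_A", "threshold_B"))
  chk(cfg$threshold_B <= cfg$s_hi, "threshold_B")
  chk(cfg$benefit_slope >= 0, "benefit_slope")
  chk(cfg$overload_slope > cfg$benefit_slope,
      c("overload_slope", "benefit_slope"))
  chk(cfg$stress_forage_coeff >= 0 && cfg$stress_forage_coeff <= 1,
      "stress_forage_coeff")
  chk(cfg$need_mean > 0, "need_mean")
  chk(cfg$need_sd >= 0, "need_sd")
  chk(cfg$rank_levels >= 1, "rank_levels")
  chk(cfg$rank_weight_lo > 0, "rank_weight_lo")
  chk(cfg$rank_weight_hi >= cfg$rank_weight_lo,
      c("rank_weight_lo", "rank_weight_hi"))
  chk(cfg$cond_max > 0, "cond_max")
  chk(cfg$cond_birth_sd >= 0, "cond_birth_sd")
  chk(cfg$repro_floor < cfg$repro_exempt && cfg$repro_exempt <= cfg$cond_max,
      c("repro_floor", "repro_exempt"))
  chk(cfg$repro_cost_cap >= 0, "repro_cost_cap")
  chk(cfg$cost_rule %in% c("floor", "half"), "cost_rule")
  chk(cfg$maxage_mean_months > 0, "maxage_mean_months")
  chk(cfg$maxage_sd_months >= 0, "maxage_sd_months")
  chk(cfg$init_pop_size >= 1, "init_pop_size")
  chk(cfg$sim_years >= 1, "sim_years")
  chk(cfg$cap_mode %in% c("ratio", "scaled"), "cap_mode")
  if (length(bad)) {
    abort(paste0("invalid config value(s) for key(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  cfg$peak_month <- as.integer(cfg$peak_month)
  cfg$rank_levels <- as.integer(cfg$rank_levels)
  cfg$init_pop_size <- as.integer(cfg$init_pop_size)
  cfg$sim_years <- as.integer(cfg$sim_years)
  structure(cfg, class = "stress_config")
}

#' @export
print.stress_config <- function(x, ...) {
  cat("<stress_config>\n")
  cat(sprintf("  stress: mean %g, sd %g on [%g, %g] (%s)\n",
              x$s_mean, x$s_sd, x$s_lo, x$s_hi, x$truncation))
  cat(sprintf("  thresholds: A = %g, B = %g; slopes %g / %g\n",
              x$threshold_A, x$threshold_B, x$benefit_slope, x$overload_slope))
  cat(sprintf("  energy: mean %g +/- %g (%s), share cap %g\n",
              x$env_mean, x$env_amplitude,
              if (x$seasonal) "seasonal" else "constant", x$share_cap))
  cat(sprintf("  run: %d individuals, %d years, peak month %d\n",
              x$init_pop_size, x$sim_years, x$peak_month))
  invisible(x)
}

#' Perturbation scenario
#'
#' Describes a transitory change in the stress regime: either no change
#' (`"baseline"`), a uniform shift of every individual's existing stress
#' impact by `delta` (`"intensity"`: the same stressors, stronger or
#' weaker), or a fresh redraw of every individual's stress around the
#' shifted mean (`"redistribution"`: a novel stressor that re-assorts who
#' copes well). The change lasts `duration_years` starting at the first
#' month of `start_year`, after which surviving individuals regain their
#' pre-perturbation stress levels.
#'
#' @param kind One of `"baseline"`, `"intensity"`, `"redistribution"`.
#' @param delta Signed shift in stress units (ignored for baseline).
#' @param start_year Calendar year (0-based) at which the change begins.
#' @param duration_years Length of the perturbation window in years.
#' @return A list of class `"scenario_spec"`.
#' @examples
#' scenario_spec("intensity", delta = 5)
#' @export
scenario_spec <- function(kind = c("baseline", "intensity", "redistribution"),
                          delta = 0, start_year = 10L, duration_years = 1L) {
  kind <- match.arg(kind)
  if (duration_years < 1) abort("duration_years must be >= 1")
  if (start_year < 0) abort("start_year must be >= 0")
  structure(
    list(kind = kind,
         delta = if (kind == "baseline") 0 else as.numeric(delta),
         start_year = as.integer(start_year),
         duration_years = as.integer(duration_years)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s\n", scenario_label(x)))
  if (x$kind != "baseline") {
    cat(sprintf("  years %d..%d\n", x$start_year,
                x$start_year + x$duration_years - 1L))
  }
  invisible(x)
}

#' Short human-readable label for a scenario
#'
#' @param spec A [scenario_spec()].
#' @return A string such as `"baseline"`, `"intensity+5"` or `"redist-5"`.
#' @export
scenario_label <- function(spec) {
  if (spec$kind == "baseline") return("baseline")
  stem <- if (spec$kind == "intensity") "intensity" else "redist"
  sprintf("%s%+g", stem, spec$delta)
}

#' Experiment grid specification
#'
#' The full experiment is a grid of population-mean stress levels crossed
#' with perturbation scenarios, each cell replicated under Monte Carlo.
#' Matched replicates of different scenarios share a random seed (common
#' random numbers), so perturbed and control trajectories are identical up
#' to the month the perturbation starts.
#'
#' @param s_mean_values Stress means to sweep (default `0:50`).
#' @param scenarios List of [scenario_spec()] objects (default: baseline
#'   only).
#' @param replicates Monte Carlo replicates per cell (default 20; the full
#'   published-scale design uses 100).
#' @param base_seed Integer from which all per-replicate seeds derive.
#' @return A list of class `"grid_spec"`.
#' @examples
#' grid_spec(s_mean_values = c(0, 25, 50), replicates = 3)
#' @export
grid_spec <- function(s_mean_values = 0:50,
                      scenarios = list(scenario_spec("baseline")),
                      replicates = 20L, base_seed = 1L) {
  if (replicates < 1) abort("replicates must be >= 1")
  if (any(s_mean_values < 0 | s_mean_values > 50)) {
    abort("s_mean_values must lie within [0, 50]")
  }
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  structure(
    list(s_mean_values = as.numeric(s_mean_values), scenarios = scenarios,
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed)),
    class = "grid_spec"
  )
}
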