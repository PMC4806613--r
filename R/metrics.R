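#' Yearly summaries of a simulation run
#'
#' Collapses a run to one record per simulated year: the population size
#' sampled at the seasonal peak (reproduction) month — chosen so size and
#' breeder metrics describe the same census — and the mean condition and
#' age of that year's breeders at the moment of reproduction. Years with
#' no breeders report `NA` for the breeder means (never zero, which would
#' bias downstream averages).
#'
#' @param result A `"stress_run"` from [run_simulation()].
#' @return A tibble with columns `year` (0-based), `pop_size`,
#'   `n_breeders`, `mean_breeder_condition`, `mean_breeder_age` (months),
#'   `births`.
#' @examples
#' run <- run_simulation(model_config(sim_years = 3, init_pop_size = 50),
#'                       seed = 1)
#' yearly_summaries(run)
#' @export
yearly_summaries <- function(result) {
  stopifnot(inherits(result, "stress_run"))
  cfg <- result$cfg
  years <- seq_len(cfg$sim_years) - 1L
  peak_rows <- years * 12L + cfg$peak_month + 1L
  br <- result$breeders |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n_breeders = dplyr::n(),
                     mean_breeder_condition = mean(.data$condition),
                     mean_breeder_age = mean(.data$age_months),
                     .groups = "drop")
  tibble::tibble(year = years,
                 pop_size = result$monthly$pop_size[peak_rows]) |>
    dplyr::left_join(br, by = "year") |>
    dplyr::left_join(result$births, by = "year") |>
    dplyr::mutate(n_breeders = dplyr::coalesce(.data$n_breeders, 0L),
                  births = dplyr::coalesce(.data$births, 0L))
}

#' Figure-style tables from a grid result
#'
#' Builds the machine-readable equivalent of the standard result panels:
#' for every (s_mean, scenario) cell, breeder condition and breeder age in
#' a small set of index years — by default the year before a year-10
#' perturbation (9), the perturbation year (10), the year after
#' restoration (11), and ten years after restoration (21) — plus the full
#' yearly mean population-size trajectories.
#'
#' @param grid A `"stress_grid"` from [run_grid()] (run with
#'   `keep_yearly = TRUE`).
#' @param years Index years (0-based) for the condition/age panel.
#' @return A list of two tibbles: `panel` (one row per cell, columns
#'   `condition_y<year>` and `age_y<year>`) and `trajectories`
#'   (s_mean, scenario, year, mean_pop_size).
#' @export
figure_tables <- function(grid, years = c(9L, 10L, 11L, 21L)) {
  stopifnot(inherits(grid, "stress_grid"))
  if (is.null(grid$yearly)) abort("grid was run without yearly summaries")
  max_year <- max(grid$yearly$year)
  if (any(years < 0 | years > max_year)) {
    abort(sprintf("requested year(s) outside the simulated range 0..%d",
                  max_year))
  }
  panel <- grid$yearly |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::select("s_mean", "scenario", "year",
                  condition = "mean_breeder_condition",
                  age = "mean_breeder_age") |>
    tidyr::pivot_wider(names_from = "year",
                       values_from = c("condition", "age"),
                       names_glue = "{.value}_y{year}")
  trajectories <- grid$yearly |>
    dplyr::select("s_mean", "scenario", "year", "mean_pop_size")
  list(panel = panel, trajectories = trajectories)
}

#' Read a configuration file
#'
#' Parses a flat YAML (or JSON — YAML is a superset) configuration into a
#' validated [model_config()] and, if a `grid` block is present, a
#' [grid_spec()]. Every model key is optional and falls back to its
#' documented default; unknown keys are an error naming the offender. An
#' empty file yields the full default configuration.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `cfg` (a `stress_config`) and `grid` (a
#'   `grid_spec`, or `NULL` when the file has no `grid` block).
#' @examples
#' tmp <- tempfile(fileext = ".yaml")
#' writeLines("s_mean: 10\nsim_years: 5", tmp)
#' read_config(tmp)$cfg$s_mean
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config file must contain a mapping")
  grid_block <- raw$grid
  raw$grid <- NULL
  cfg <- do.call(model_config, raw)
  grid <- NULL
  if (!is.null(grid_block)) {
    known <- c("s_mean_values", "scenarios", "replicates", "base_seed")
    unknown <- setdiff(names(grid_block), known)
    if (length(unknown)) {
      abort(paste0("unknown grid key(s): ", paste(unknown, collapse = ", ")))
    }
    scs <- grid_block$scenarios
    scenarios <- if (is.null(scs)) list(scenario_spec("baseline")) else
      lapply(scs, function(s) do.call(scenario_spec, s))
    grid <- grid_spec(
      s_mean_values = grid_block$s_mean_values %||% 0:50,
      scenarios = scenarios,
      replicates = grid_block$replicates %||% 20L,
      base_seed = grid_block$base_seed %||% 1L)
  }
  list(cfg = cfg, grid = grid)
}

#' Write a configuration file
#'
#' Serialises a [model_config()] (and optionally a [grid_spec()]) to flat
#' YAML that [read_config()] reads back identically.
#'
#' @param cfg A `stress_config`.
#' @param path Output path.
#' @param grid Optional `grid_spec`.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path, grid = NULL) {
  stopifnot(inherits(cfg, "stress_config"))
  out <- unclass(cfg)
  if (!is.null(grid)) {
    out$grid <- list(
      s_mean_values = grid$s_mean_values,
      replicates = grid$replicates,
      base_seed = grid$base_seed,
      scenarios = lapply(grid$scenarios, function(s) unclass(s)))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write run outputs to disk
#'
#' Serialises one run as plain text: `monthly.csv` (month, pop_size),
#' `breeders.csv` (year, id, age_months, condition; breeder means for a
#' year with no breeders are simply absent rather than zero), and
#' `summary.json` (extinction status, yearly summaries, seed and a config
#' digest). Byte-identical across re-runs of the same (config, seed).
#'
#' @param result A `"stress_run"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_result <- function(result, dir) {
  stopifnot(inherits(result, "stress_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$monthly, file.path(dir, "monthly.csv"),
                   row.names = FALSE)
  utils::write.csv(result$breeders, file.path(dir, "breeders.csv"),
                   row.names = FALSE)
  ys <- yearly_summaries(result)
  summary <- list(
    extinct = result$extinct,
    extinction_month = if (result$extinct) result$extinction_month else NULL,
    seed = result$seed,
    scenario = scenario_label(result$scenario),
    config_digest = config_digest(result$cfg),
    yearly = ys)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(dir)
}

#' Write grid outputs to disk
#'
#' Writes the per-cell aggregate table (`grid_summary.csv`), the
#' per-replicate final sizes (`finals.csv`) and, when present, the yearly
#' trajectories (`yearly.csv`). Missing breeder statistics are written as
#' empty fields, never zero.
#'
#' @param grid A `"stress_grid"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_grid_result <- function(grid, dir) {
  stopifnot(inherits(grid, "stress_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(grid$cells, file.path(dir, "grid_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(grid$finals, file.path(dir, "finals.csv"),
                   row.names = FALSE)
  if (!is.null(grid$yearly)) {
    utils::write.csv(grid$yearly, file.path(dir, "yearly.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

# short stable digest of a config (order-independent of list storage)
config_digest <- function(cfg) {
  keys <- sort(names(cfg))
  txt <- paste(keys, vapply(cfg[keys], function(v) paste(format(v),
                                                         collapse = ","),
                            character(1)),
               sep = "=", collapse = ";")
  # tiny rolling hash (exact in doubles below 2^53); no extra deps
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
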