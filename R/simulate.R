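#' Advance a population by one month
#'
#' One tick of the simulator, in fixed order: (1) look up the environmental
#' energy for the current month; (2) count the living population `P_t`;
#' (3) give every individual its foraging gain at that common `P_t`;
#' (4) update conditions; (5) remove deaths — condition at or below zero,
#' or age beyond the individual's maximal age; (6) if this is the seasonal
#' peak month, run [annual_reproduction()]; (7) advance the clock. An empty
#' population only advances the clock (no immigration, so extinction is
#' absorbing).
#'
#' @param pop A `"stress_pop"` tibble (see [init_population()]).
#' @param cfg A [model_config()].
#' @param log_events If `TRUE`, attach a per-individual event tibble
#'   (`month`, `id`, `gain`, `cond_after`) as attribute `"events"` for
#'   replay audits.
#' @return The population one month later; dead individuals are dropped.
#'   Attribute `"breeders"` carries that month's breeder records (or
#'   `NULL`), `"deaths"` the ids that died.
#' @export
monthly_step <- function(pop, cfg, log_events = FALSE) {
  t <- pop_month(pop)
  next_id <- attr(pop, "next_id")
  pert <- attr(pop, "perturbation")
  breeders <- NULL
  events <- NULL
  deaths <- integer(0)
  if (nrow(pop) > 0L) {
    p_t <- pop_size(pop)
    gain <- foraging_gain(pop, pop_size = p_t, env_e = env_energy(t, cfg),
                          cfg = cfg)
    pop <- condition_update(pop, gain, cfg)
    # deaths: starvation, or ageing past the individual cut-off this month
    age_now <- t + 1L - pop$birth_month
    dead <- pop$condition <= 0 | age_now > pop$max_age_months
    deaths <- pop$id[dead]
    pop$alive[dead] <- FALSE
    if (log_events) {
      events <- tibble::tibble(month = t, id = pop$id, gain = gain,
                               cond_after = pop$condition)
    }
    pop <- pop[!dead, , drop = FALSE]
    if (nrow(pop) > 0L && t %% 12L == cfg$peak_month) {
      pop <- new_stress_pop(pop, month = t, next_id = next_id,
                            perturbation = pert)
      pop <- annual_reproduction(pop, cfg)
      breeders <- attr(pop, "breeders")
      next_id <- attr(pop, "next_id")
    }
  }
  pop <- new_stress_pop(pop, month = t + 1L, next_id = next_id,
                        perturbation = pert)
  attr(pop, "breeders") <- breeders
  attr(pop, "deaths") <- deaths
  if (log_events) attr(pop, "events") <- events
  pop
}

#' Annual reproduction at the seasonal energy peak
#'
#' Each living individual breeds at most once a year, at the month of peak
#' environmental energy, provided its condition is at least `repro_floor`
#' *and* rose during the past month — unless condition already exceeds
#' `repro_exempt`, in which case the recent-increase requirement is waived.
#' Each breeder produces exactly one offspring (traits drawn independently
#' of the parent) and pays a condition cost:
#' `min(repro_cost_cap, condition - repro_floor)` under the default
#' `"floor"` rule, which never pushes a parent below the viability floor it
#' just demonstrated, or `min(repro_cost_cap, condition / 2)` under
#' `"half"`. During a redistribution or intensity window, newborns draw
#' their stress around the shifted population mean.
#'
#' @param pop A `"stress_pop"` tibble at the peak month.
#' @param cfg A [model_config()].
#' @return The population with offspring appended; attribute `"breeders"`
#'   is a tibble of `id`, `age_months` and `condition` (at reproduction,
#'   before the cost) for that year's breeders.
#' @export
annual_reproduction <- function(pop, cfg) {
  t <- pop_month(pop)
  pert <- attr(pop, "perturbation")
  next_id <- attr(pop, "next_id")
  eligible <- pop$alive &
    ((pop$condition >= cfg$repro_floor & pop$condition > pop$condition_prev) |
       pop$condition > cfg$repro_exempt)
  breeders <- tibble::tibble(
    id = pop$id[eligible],
    age_months = t - pop$birth_month[eligible],
    condition = pop$condition[eligible]
  )
  n_off <- sum(eligible)
  if (n_off > 0L) {
    cost <- if (cfg$cost_rule == "floor") {
      pmin(cfg$repro_cost_cap,
           pmax(0, pop$condition[eligible] - cfg$repro_floor))
    } else {
      pmin(cfg$repro_cost_cap, pop$condition[eligible] / 2)
    }
    pop$condition[eligible] <- pop$condition[eligible] - cost
    s_mean_eff <- if (is.null(pert)) cfg$s_mean else pert$newborn_mean
    kids <- spawn_individuals(n_off, cfg, s_mean = s_mean_eff,
                              birth_month = t, first_id = next_id)
    pop <- dplyr::bind_rows(pop, kids)
    next_id <- next_id + n_off
  }
  pop <- new_stress_pop(pop, month = t, next_id = next_id,
                        perturbation = pert)
  attr(pop, "breeders") <- breeders
  pop
}

#' Apply a transitory stress perturbation
#'
#' Starts a perturbation window. Every living individual's current stress
#' is saved for later restoration, then either shifted by `delta` and
#' clamped to the stress bounds (`"intensity"`: the same stressors,
#' stronger or weaker) or redrawn from a truncated normal around the
#' shifted population mean (`"redistribution"`: a novel stressor that
#' re-assorts which individuals cope well). Newborns during the window draw
#' their stress around the shifted mean.
#'
#' @param pop A `"stress_pop"` tibble with no perturbation active.
#' @param spec A [scenario_spec()] of kind `"intensity"` or
#'   `"redistribution"` (a `"baseline"` spec is a no-op).
#' @param cfg A [model_config()].
#' @return The perturbed population; the active perturbation is tracked as
#'   an attribute until [restore_perturbation()].
#' @export
apply_perturbation <- function(pop, spec, cfg) {
  if (spec$kind == "baseline") return(pop)
  if (!is.null(attr(pop, "perturbation"))) {
    abort("a perturbation is already active; restore it first")
  }
  pop$stress_saved <- pop$stress
  if (spec$kind == "intensity") {
    pop$stress <- pmin(pmax(pop$stress + spec$delta, cfg$s_lo), cfg$s_hi)
  } else {
    pop$stress <- draw_truncated_normal(nrow(pop), cfg$s_mean + spec$delta,
                                        cfg$s_sd, cfg$s_lo, cfg$s_hi,
                                        cfg$truncation)
  }
  new_stress_pop(pop, month = pop_month(pop), next_id = attr(pop, "next_id"),
                 perturbation = list(kind = spec$kind, delta = spec$delta,
                                     newborn_mean = cfg$s_mean + spec$delta))
}

#' Restore pre-perturbation stress levels
#'
#' Ends the active perturbation window: individuals alive since before the
#' perturbation regain their saved stress impact; individuals born during
#' the window have no saved value and keep the stress they were drawn with.
#'
#' @param pop A `"stress_pop"` tibble with an active perturbation.
#' @return The restored population.
#' @export
restore_perturbation <- function(pop) {
  if (is.null(attr(pop, "perturbation"))) {
    abort("no active perturbation to restore")
  }
  saved <- !is.na(pop$stress_saved)
  pop$stress[saved] <- pop$stress_saved[saved]
  pop$stress_saved <- NA_real_
  new_stress_pop(pop, month = pop_month(pop), next_id = attr(pop, "next_id"),
                 perturbation = NULL)
}

#' Run one full simulation
#'
#' Initialises a population and advances it month by month for
#' `cfg$sim_years` years, applying and later reversing the scenario's
#' perturbation at the configured calendar years. Identical
#' `(cfg, scenario, seed)` give bit-identical results, and runs that share
#' a seed share their trajectory exactly until the perturbation starts
#' (common random numbers).
#'
#' @param cfg A [model_config()].
#' @param scenario A [scenario_spec()]; default baseline.
#' @param seed Integer seed for this run (default `cfg$seed`). The global
#'   RNG state is left untouched.
#' @param log_events If `TRUE`, keep a per-individual monthly event log
#'   (gain, condition, reproduction cost) for replay audits; costly, meant
#'   for small runs.
#' @return An object of class `"stress_run"`: a list with tibbles
#'   `monthly` (month, pop_size), `breeders` (year, id, age_months,
#'   condition), `births` (year, births), flags `extinct` /
#'   `extinction_month`, and the generating `cfg`, `scenario`, `seed`.
#' @examples
#' cfg <- model_config(s_mean = 10, sim_years = 3, init_pop_size = 50)
#' run <- run_simulation(cfg, seed = 1)
#' glance(run)
#' @export
run_simulation <- function(cfg, scenario = scenario_spec("baseline"),
                           seed = cfg$seed, log_events = FALSE) {
  stopifnot(inherits(cfg, "stress_config"), inherits(scenario, "scenario_spec"))
  with_local_seed(seed, {
    months_total <- cfg$sim_years * 12L
    pert_start <- scenario$start_year * 12L
    pert_end <- (scenario$start_year + scenario$duration_years) * 12L
    perturbing <- scenario$kind != "baseline" && pert_start < months_total

    pop <- init_population(cfg)
    sizes <- integer(months_total)
    breeders <- vector("list", cfg$sim_years)
    births <- integer(cfg$sim_years)
    costs <- if (log_events) vector("list", cfg$sim_years) else NULL
    events <- if (log_events) vector("list", months_total) else NULL

    for (t in seq_len(months_total) - 1L) {
      if (perturbing && t == pert_start) {
        pop <- apply_perturbation(pop, scenario, cfg)
      }
      if (perturbing && t == pert_end) {
        pop <- restore_perturbation(pop)
      }
      pop <- monthly_step(pop, cfg, log_events = log_events)
      sizes[t + 1L] <- pop_size(pop)
      br <- attr(pop, "breeders")
      if (!is.null(br) && nrow(br)) {
        yr <- t %/% 12L + 1L
        br$year <- t %/% 12L
        breeders[[yr]] <- br
        births[yr] <- births[yr] + nrow(br)
        if (log_events) {
          costs[[yr]] <- tibble::tibble(
            month = t, id = br$id,
            cost = repro_cost(br$condition, cfg))
        }
      }
      if (log_events) events[[t + 1L]] <- attr(pop, "events")
    }

    monthly <- tibble::tibble(month = seq_len(months_total) - 1L,
                              pop_size = sizes)
    ext_month <- if (any(sizes == 0L)) which(sizes == 0L)[1L] - 1L else
      NA_integer_
    br_all <- dplyr::bind_rows(breeders)
    if (!nrow(br_all)) {
      br_all <- tibble::tibble(year = integer(), id = integer(),
                               age_months = integer(), condition = numeric())
    }
    res <- list(
      monthly = monthly,
      breeders = br_all[, c("year", "id", "age_months", "condition")],
      births = tibble::tibble(year = seq_len(cfg$sim_years) - 1L,
                              births = births),
      extinct = !is.na(ext_month),
      extinction_month = ext_month,
      cfg = cfg, scenario = scenario, seed = as.integer(seed)
    )
    if (log_events) {
      res$events <- dplyr::bind_rows(events)
      res$repro_costs <- dplyr::bind_rows(costs)
    }
    structure(res, class = "stress_run")
  })
}

# reproduction cost charged to a breeder at pre-cost condition `cond`
repro_cost <- function(cond, cfg) {
  if (cfg$cost_rule == "floor") {
    pmin(cfg$repro_cost_cap, pmax(0, cond - cfg$repro_floor))
  } else {
    pmin(cfg$repro_cost_cap, cond / 2)
  }
}

# evaluate `expr` under `seed` without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @export
print.stress_run <- function(x, ...) {
  cat(sprintf("<stress_run> %s, s_mean %g, %d years, seed %d\n",
              scenario_label(x$scenario), x$cfg$s_mean, x$cfg$sim_years,
              x$seed))
  final <- tail(x$monthly$pop_size, 1)
  cat(sprintf("  final size %d%s, %d breeding events\n", final,
              if (x$extinct) sprintf(" (extinct at month %d)",
                                     x$extinction_month) else "",
              nrow(x$breeders)))
  invisible(x)
}
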