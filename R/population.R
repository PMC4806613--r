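#' Truncated normal draws
#'
#' Draws from a normal distribution restricted to `[lo, hi]`. The default
#' `"clamp"` method clips out-of-range draws to the nearest bound, so
#' probability mass accumulates at the bounds — the behaviour used for the
#' individual stress impact, where a population mean pushed past a bound
#' piles individuals up at the extreme. `"redraw"` rejection-samples
#' instead, giving a classical truncated normal with no atoms.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal; `sd = 0` returns
#'   `clamp(mean)` exactly.
#' @param lo,hi Truncation bounds, `lo < hi`.
#' @param method `"clamp"` (default) or `"redraw"`.
#' @return Numeric vector of length `n`, all values in `[lo, hi]`.
#' @examples
#' set.seed(1)
#' summary(draw_truncated_normal(1000, mean = 0, sd = 15, lo = 0, hi = 50))
#' @export
draw_truncated_normal <- function(n, mean, sd, lo, hi,
                                  method = c("clamp", "redraw")) {
  method <- match.arg(method)
  if (lo >= hi) abort("invalid truncation bounds: lo must be < hi")
  if (sd < 0) abort("sd must be >= 0")
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  if (method == "clamp") {
    return(pmin(pmax(rnorm(n, mean, sd), lo), hi))
  }
  # rejection sampling; the acceptance region always has positive mass
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# smallest positive condition / need: open lower bounds are realised by
# clamping to an epsilon above zero so no trait is drawn exactly at death
.trait_eps <- 1e-8

#' Draw newborn individuals
#'
#' Creates `n` individuals with traits drawn independently from the
#' configured distributions: stress impact around `s_mean` (truncated to
#' the 0--50 scale), condition at birth around `cond_birth_mean` on
#' (0, `cond_max`], a uniform foraging rank, a positive baseline energy
#' need, and a maximal age in whole months. Offspring traits never depend
#' on the parent.
#'
#' @param n Number of individuals to create.
#' @param cfg A [model_config()].
#' @param s_mean Effective population stress mean for these births (during
#'   a redistribution window this is the shifted mean; defaults to
#'   `cfg$s_mean`).
#' @param birth_month Global month index stamped on each newborn (may be
#'   negative for the staggered founder cohort).
#' @param first_id Identifier of the first newborn; ids are consecutive.
#' @return A tibble with one row per individual and columns `id`,
#'   `birth_month`, `forage_rank`, `stress`, `baseline_need`,
#'   `max_age_months`, `condition`, `condition_prev`, `alive`,
#'   `stress_saved`.
#' @examples
#' set.seed(1)
#' spawn_individuals(3, model_config(s_mean = 10))
#' @export
spawn_individuals <- function(n, cfg, s_mean = cfg$s_mean, birth_month = 0L,
                              first_id = 1L) {
  n <- as.integer(n)
  stress <- draw_truncated_normal(n, s_mean, cfg$s_sd, cfg$s_lo, cfg$s_hi,
                                  cfg$truncation)
  condition <- draw_truncated_normal(n, cfg$cond_birth_mean, cfg$cond_birth_sd,
                                     .trait_eps, cfg$cond_max, cfg$truncation)
  rank <- if (cfg$rank_levels == 1L) rep(1L, n) else
    sample.int(cfg$rank_levels, n, replace = TRUE)
  need <- draw_truncated_normal(n, cfg$need_mean, cfg$need_sd, .trait_eps, Inf,
                                cfg$truncation)
  max_age <- as.integer(floor(draw_truncated_normal(
    n, cfg$maxage_mean_months, cfg$maxage_sd_months, 1 + .trait_eps, Inf,
    cfg$truncation) + 0.5))
  tibble::tibble(
    id = first_id + seq_len(n) - 1L,
    birth_month = rep(as.integer(birth_month), n),
    forage_rank = rank,
    stress = stress,
    baseline_need = need,
    max_age_months = max_age,
    condition = condition,
    condition_prev = condition,
    alive = rep(TRUE, n),
    stress_saved = rep(NA_real_, n)
  )
}

#' Initialise a population
#'
#' Creates the founding population at month 0: `init_pop_size` individuals
#' drawn via [spawn_individuals()] at the configured stress mean, with
#' birth months staggered uniformly over one mean lifespan into the past so
#' the founders do not senesce in lockstep.
#'
#' @param cfg A [model_config()].
#' @return A tibble of individuals of class `"stress_pop"`, carrying the
#'   current month, the next free id and the active perturbation (none) as
#'   attributes.
#' @examples
#' set.seed(1)
#' pop <- init_population(model_config(init_pop_size = 50))
#' nrow(pop)
#' @export
init_population <- function(cfg) {
  if (cfg$init_pop_size < 1) abort("init_pop_size must be >= 1")
  pop <- spawn_individuals(cfg$init_pop_size, cfg, s_mean = cfg$s_mean,
                           birth_month = 0L, first_id = 1L)
  # stagger founder ages so max-age mortality is spread over a lifespan
  pop$birth_month <- -as.integer(floor(runif(nrow(pop), 0,
                                             cfg$maxage_mean_months)))
  new_stress_pop(pop, month = 0L, next_id = cfg$init_pop_size + 1L)
}

new_stress_pop <- function(pop, month, next_id, perturbation = NULL) {
  structure(pop, month = as.integer(month), next_id = as.integer(next_id),
            perturbation = perturbation,
            class = c("stress_pop", class(tibble::tibble())))
}

#' Current month of a population state
#' @param pop A `"stress_pop"` tibble.
#' @return Integer global month index.
#' @export
pop_month <- function(pop) attr(pop, "month")

#' Number of living individuals
#' @param pop A `"stress_pop"` tibble.
#' @return Integer count of rows with `alive = TRUE`.
#' @export
pop_size <- function(pop) sum(pop$alive)

#' @export
print.stress_pop <- function(x, ...) {
  cat(sprintf("<stress_pop> month %d, %d alive\n", pop_month(x), pop_size(x)))
  NextMethod()
}
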