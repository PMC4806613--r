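#' Environmental energy cycle
#'
#' Total energy available in the environment at a given month. With
#' `seasonal = FALSE` the supply is constant at `env_mean`. Otherwise it
#' follows a triangular annual wave: a constant monthly rate of increase
#' over six months up to `env_mean + env_amplitude` at `peak_month`, then a
#' constant rate of decrease over six months down to
#' `env_mean - env_amplitude`. The 12-month mean is exactly `env_mean`, so
#' seasonal and constant regimes are energetically equivalent over a year.
#'
#' @param month Global month index (vectorised, `>= 0`).
#' @param cfg A [model_config()].
#' @return Energy available that month (energy/month).
#' @examples
#' cfg <- model_config(env_mean = 3000, env_amplitude = 600, peak_month = 5)
#' env_energy(0:11, cfg)
#' @export
env_energy <- function(month, cfg) {
  if (any(month < 0)) abort("month must be >= 0")
  if (!cfg$seasonal) return(rep(cfg$env_mean, length(month)))
  d <- (month - cfg$peak_month) %% 12
  tri <- ifelse(d <= 6, 1 - d / 3, -3 + d / 3)
  cfg$env_mean + cfg$env_amplitude * tri
}

#' Foraging-rank weight
#'
#' Maps an individual's constant foraging rank onto a multiplicative
#' foraging-success weight, linearly from `rank_weight_lo` (rank 1) to
#' `rank_weight_hi` (rank `rank_levels`). Ranks are not unique, so tied
#' individuals get identical weights. With a single rank level every
#' individual receives `rank_weight_hi`.
#'
#' @param forage_rank Integer rank(s) in `1:rank_levels`.
#' @param cfg A [model_config()].
#' @return Numeric weight(s), strictly increasing in rank.
#' @examples
#' rank_weight(c(1, 10), model_config())
#' @export
rank_weight <- function(forage_rank, cfg) {
  if (any(forage_rank < 1 | forage_rank > cfg$rank_levels)) {
    abort("forage_rank outside 1..rank_levels")
  }
  if (cfg$rank_levels == 1L) return(rep(cfg$rank_weight_hi,
                                        length(forage_rank)))
  cfg$rank_weight_lo + (forage_rank - 1) / (cfg$rank_levels - 1) *
    (cfg$rank_weight_hi - cfg$rank_weight_lo)
}

#' Monthly foraging gain
#'
#' Energy an individual actually obtains in one month. The per-capita share
#' of the environmental supply, `env_e / pop_size`, is capped at
#' `share_cap` (a resource saturation point beyond which richer
#' environments bring no further benefit), then scaled by the individual's
#' rank weight and reduced in proportion to its stress impact:
#' \deqn{F_p(t) = \min(EnvE/P_t,\; cap) \times w(FRank_p) \times
#'   (1 - c\, S_p / S_{hi}).}
#' Gain therefore falls as the population grows (density dependence) and as
#' stress rises.
#'
#' @param pop A tibble of individuals (needs columns `forage_rank` and
#'   `stress`), or any data frame subset of one.
#' @param pop_size Total living population size used for the per-capita
#'   share (`>= 1`).
#' @param env_e Environmental energy this month (`>= 0`).
#' @param cfg A [model_config()].
#' @return Numeric vector of energy gains, one per row of `pop`.
#' @examples
#' cfg <- model_config()
#' ind <- tibble::tibble(forage_rank = 10L, stress = 0)
#' foraging_gain(ind, pop_size = 10, env_e = 1e6, cfg)
#' @export
foraging_gain <- function(pop, pop_size, env_e, cfg) {
  if (pop_size < 1) abort("pop_size must be >= 1: no foraging in an extinct population")
  if (env_e < 0) abort("env_e must be >= 0")
  share <- if (cfg$cap_mode == "ratio") {
    pmin(env_e / pop_size, cfg$share_cap)
  } else {
    pmin(cfg$share_cap * env_e / pop_size, env_e)
  }
  share * rank_weight(pop$forage_rank, cfg) *
    (1 - cfg$stress_forage_coeff * pop$stress / cfg$s_hi)
}

#' Net stress-energy term
#'
#' The physiological response to stressors acts twice on an individual's
#' energy budget: it raises energy needs (the cost of mounting a response)
#' and it slows energy consumption (the compensatory saving). Only their
#' difference enters the condition dynamics, and it is piecewise linear in
#' the stress impact `s`:
#' \itemize{
#'   \item `s < A`: compensation outpaces the extra need — a net energy
#'     benefit of `benefit_slope * (A - s)` (returned as a negative cost);
#'   \item `A <= s <= B`: the two effects cancel exactly — net zero;
#'   \item `s > B`: needs run away — a net cost of
#'     `overload_slope * (s - B)`, with `overload_slope` well above
#'     `benefit_slope`.
#' }
#' The function is continuous at both thresholds and nondecreasing.
#'
#' @param s Stress impact(s) in `[0, 50]` (vectorised).
#' @param params Anything carrying `threshold_A`, `threshold_B`,
#'   `benefit_slope`, `overload_slope` — typically a [model_config()] or
#'   [stress_energy_params()].
#' @return Net monthly energy cost (energy/month; negative = net benefit).
#' @examples
#' net_stress_energy(c(0, 15, 25, 35, 45), model_config())
#' @export
net_stress_energy <- function(s, params) {
  if (any(s < 0 | s > 50)) abort("stress must lie in [0, 50]")
  A <- params$threshold_A
  B <- params$threshold_B
  ifelse(s < A, -params$benefit_slope * (A - s),
         ifelse(s > B, params$overload_slope * (s - B), 0))
}

#' Stress-energy parameter bundle
#'
#' Convenience constructor for the four constants of the two-threshold
#' compensation model, for use with [net_stress_energy()] outside a full
#' [model_config()].
#'
#' @param threshold_A,threshold_B Compensation thresholds on the stress
#'   scale, `A <= B`.
#' @param benefit_slope,overload_slope Net energy per stress unit below A
#'   and above B; `overload_slope > benefit_slope >= 0`.
#' @return A list of class `"stress_energy_params"`.
#' @export
stress_energy_params <- function(threshold_A = 15, threshold_B = 35,
                                 benefit_slope = 0.05, overload_slope = 0.3) {
  if (threshold_A > threshold_B) abort("threshold_A must be <= threshold_B")
  if (!(overload_slope > benefit_slope && benefit_slope >= 0)) {
    abort("need overload_slope > benefit_slope >= 0")
  }
  structure(list(threshold_A = threshold_A, threshold_B = threshold_B,
                 benefit_slope = benefit_slope,
                 overload_slope = overload_slope),
            class = "stress_energy_params")
}

#' Monthly condition update
#'
#' Advances each individual's physical condition by one month of energy
#' balance: intake minus baseline need minus the net stress-energy term,
#' capped at `cond_max` (condition is bounded above by the full range;
#' there is no lower bound — death at `<= 0` is decided by the simulator).
#'
#' @param pop A tibble of individuals (columns `condition`, `baseline_need`,
#'   `stress`).
#' @param gain Foraging gain per individual (energy/month), as from
#'   [foraging_gain()].
#' @param cfg A [model_config()].
#' @return `pop` with `condition` advanced and `condition_prev` set to the
#'   pre-update condition.
#' @export
condition_update <- function(pop, gain, cfg) {
  pop$condition_prev <- pop$condition
  pop$condition <- pmin(
    cfg$cond_max,
    pop$condition + gain - pop$baseline_need - net_stress_energy(pop$stress, cfg)
  )
  pop
}
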