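# Small, fast configurations for unit tests. The reduced energy supply keeps
# censuses in the low hundreds so multi-year runs stay cheap; dynamics are
# otherwise the package defaults.
small_cfg <- function(...) {
  args <- modifyList(list(env_mean = 300, env_amplitude = 10,
                          init_pop_size = 50L, sim_years = 10L), list(...))
  do.call(model_config, args)
}

# A deterministic single-phenotype config: every trait distribution has zero
# spread, one foraging rank with weight 1, constant environment. With
# `per_capita` energy per head and `need`, each individual's monthly balance
# is exactly per_capita - need - net(s_mean).
degenerate_cfg <- function(n = 1L, per_capita = 6, need = 6, s_mean = 25,
                           ...) {
  model_config(
    env_mean = per_capita * n, env_amplitude = 0, seasonal = FALSE,
    s_mean = s_mean, s_sd = 1e-9,
    need_mean = need, need_sd = 0,
    rank_levels = 1L, rank_weight_lo = 1, rank_weight_hi = 1,
    stress_forage_coeff = 0,
    cond_birth_sd = 0,
    maxage_mean_months = 1200L,  # age cut-off far beyond the horizon
    maxage_sd_months = 0L,
    init_pop_size = as.integer(n),
    ...
  )
}

# mean of a normal(mean, sd) clamped to [lo, hi] in closed form
clamped_normal_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mean * (pnorm(b) - pnorm(a)) - sd * (dnorm(b) - dnorm(a))
}

# SD of the clamped normal by numerical integration of the continuous part
clamped_normal_sd <- function(mean, sd, lo, hi) {
  m1 <- clamped_normal_mean(mean, sd, lo, hi)
  cont <- stats::integrate(function(x) x^2 * dnorm(x, mean, sd), lo, hi,
                           rel.tol = 1e-10)$value
  m2 <- lo^2 * pnorm((lo - mean) / sd) +
    hi^2 * (1 - pnorm((hi - mean) / sd)) + cont
  sqrt(m2 - m1^2)
}
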