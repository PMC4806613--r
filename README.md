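# stresspop

An individual-based simulator of wild-animal populations under chronic
physiological stress, for conservation physiologists and population
modellers who want to ask: *at what point does more stress start to cost a
population, and what does a stressed population look like before it
declines?*

Each simulated animal carries an aggregate stress impact $S_p$ on a 0–50
scale, a foraging rank, a baseline energy need and a maximal age. Monthly
foraging is density dependent and stress-penalised,

$$F_p(t) = \min\!\left(\tfrac{EnvE(t)}{P_t},\, 10\right)\, w(FRank_p)\,
\left(1 - \tfrac{S_p}{50}\right),$$

and the physiological stress response enters the energy budget as a
piecewise-linear net term with two thresholds: below $A = 15$ coping saves
more energy than the stressors cost, between 15 and 35 the opposing flows
cancel exactly, and above $B = 35$ needs run away (homeostatic overload).
Condition (0–100) integrates the budget; death occurs at condition ≤ 0 or
past an individual age cut-off, and reproduction happens once a year at
the seasonal energy peak, gated on condition and its recent trend, at a
condition cost. From these rules the population-level patterns emerge:
final sizes inversely stratified by mean stress, three qualitative stress
regimes with a collapse near impact 36, reliance of stressed populations
on old, high-condition breeders, and characteristic responses to one-year
stress perturbations — including the counterintuitive decline after a
stress *decrease*, via density feedback, and the severity of novel
stressors modelled as a redistribution of individual impacts.

## A worked example

```r
library(stresspop)

cfg <- model_config(s_mean = 10)                     # mean stress impact 10
run <- run_simulation(cfg, scenario_spec("intensity", 5), seed = 1)
glance(run)
#> # A tibble: 1 × 8
#>   s_mean scenario    sim_years final_size extinct extinction_month total_births
#>    <dbl> <chr>           <int>      <dbl> <lgl>              <int>        <int>
#> 1     10 intensity+5        25       728. FALSE                 NA         4989
```

The population carries mean impact 10, is hit by a +5 intensity year at
year 10, and ends around 728 animals at year 25 after 4989 births. `tidy(run)` gives the
yearly census with breeder condition and age; `autoplot(run)` draws the
monthly trajectory with the perturbation window shaded.

The full experiment is a grid:

```r
g  <- grid_spec(s_mean_values = seq(0, 50, 5),
                scenarios = list(scenario_spec("baseline")),
                replicates = 20, base_seed = 1)
gr <- run_grid(g, model_config())
tidy(gr)                               # per-cell means, SDs, extinctions
classify_groups(data.frame(s_mean = gr$cells$s_mean,
                           final_size = gr$cells$mean_final_size))
#> # A tibble: 3 × 5
#>   group  s_lo  s_hi mean_size     n
#> 1     1    40    50     0.647     3
#> 2     2    35    35    24.6       1
#> 3     3     0    30   627.       7
```

Group 1 is the collapsed high-stress regime (essentially extinct on this
coarse 5-step grid), group 3 the large low-stress populations; the full
51-level grid resolves the high-stress boundary near stress 36. `recovery_time()` and `convergence_check()` quantify
perturbation recovery and Monte Carlo precision. A thin command-line
wrapper is installed as `exec/stresspop` with `simulate`, `grid` and
`report` subcommands over YAML configurations.

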