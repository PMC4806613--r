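Package: stresspop
Title: Individual-Based Stress-Energetics Population Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based, monthly-time-step simulator of wild animal
    populations under chronic physiological stress. Each animal carries a
    scalar stress impact, a foraging rank and an energy requirement; density-
    dependent foraging, a two-threshold stress-energy compensation model and
    condition-gated annual reproduction drive survival, breeding and
    extinction. The package runs stress-level grids and transitory
    perturbation experiments (intensity shifts and redistribution of
    individual stress) under Monte Carlo replication, with convergence
    diagnostics, emergent-group classification, recovery-time estimation,
    tidy summaries and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
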