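test_that("yearly summaries average breeders and flag empty years as missing", {
  cfg <- small_cfg(s_mean = 10, sim_years = 6L)
  run <- run_simulation(cfg, seed = 31)
  ys <- yearly_summaries(run)
  expect_equal(nrow(ys), 6L)
  expect_equal(ys$year, 0:5)
  # population size is the census at the peak month of each year
  expect_equal(ys$pop_size,
               run$monthly$pop_size[0:5 * 12 + cfg$peak_month + 1])
  # per-year breeder means match direct recomputation from the records
  for (y in unique(run$breeders$year)) {
    b <- run$breeders[run$breeders$year == y, ]
    expect_equal(ys$mean_breeder_condition[ys$year == y], mean(b$condition))
    expect_equal(ys$mean_breeder_age[ys$year == y], mean(b$age_months))
    expect_equal(ys$n_breeders[ys$year == y], nrow(b))
  }
  # years without breeders report missing means, never zero
  empty <- setdiff(0:5, unique(run$breeders$year))
  if (length(empty)) {
    expect_true(all(is.na(ys$mean_breeder_condition[ys$year %in% empty])))
    expect_true(all(ys$n_breeders[ys$year %in% empty] == 0L))
  }
  # a run with no reproduction at all: all means missing
  dead <- run_simulation(degenerate_cfg(n = 1, per_capita = 5, need = 6,
                                        sim_years = 3L), seed = 1)
  ys0 <- yearly_summaries(dead)
  expect_true(all(is.na(ys0$mean_breeder_condition)))
  expect_true(all(ys0$births == 0L))
})

test_that("tidy and glance expose run and grid results as tibbles", {
  cfg <- small_cfg(s_mean = 10, sim_years = 5L)
  run <- run_simulation(cfg, seed = 2)
  expect_identical(tidy(run), yearly_summaries(run))
  gl <- glance(run)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$s_mean, 10)
  expect_equal(gl$final_size, final_size(run))

  g <- grid_spec(s_mean_values = c(5, 40), replicates = 2, base_seed = 3)
  gr <- run_grid(g, cfg)
  expect_identical(tidy(gr), gr$cells)
  expect_equal(glance(gr)$n_cells, 2L)
})

test_that("figure tables pivot the index years and validate the range", {
  g <- grid_spec(s_mean_values = c(5, 30),
                 scenarios = list(scenario_spec("baseline"),
                                  scenario_spec("intensity", 5,
                                                start_year = 3L,
                                                duration_years = 1L)),
                 replicates = 2, base_seed = 7)
  cfg <- small_cfg(sim_years = 8L)
  gr <- run_grid(g, cfg)
  ft <- figure_tables(gr, years = c(2L, 3L, 4L, 7L))
  expect_named(ft, c("panel", "trajectories"))
  expect_true(all(c("condition_y2", "condition_y3", "condition_y4",
                    "condition_y7", "age_y2", "age_y7") %in%
                    names(ft$panel)))
  expect_equal(nrow(ft$panel), 4L)  # 2 stress levels x 2 scenarios
  expect_equal(nrow(ft$trajectories), 4L * 8L)
  expect_error(figure_tables(gr, years = c(2L, 99L)), "range")
  # a null perturbation produces tables identical to the baseline cells
  g0 <- grid_spec(s_mean_values = c(5, 30),
                  scenarios = list(scenario_spec("baseline"),
                                   scenario_spec("intensity", 0,
                                                 start_year = 3L)),
                  replicates = 2, base_seed = 7)
  ft0 <- figure_tables(run_grid(g0, cfg), years = c(2L, 4L))
  base <- ft0$panel[ft0$panel$scenario == "baseline",
                    setdiff(names(ft0$panel), "scenario")]
  null <- ft0$panel[ft0$panel$scenario == "intensity+0",
                    setdiff(names(ft0$panel), "scenario")]
  expect_equal(as.data.frame(base), as.data.frame(null))
})

test_that("config files round-trip and report offending keys", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", tmp)
  defaults <- read_config(tmp)
  expect_identical(unclass(defaults$cfg), unclass(model_config()))
  expect_null(defaults$grid)

  writeLines("nonsense_key: 3", tmp)
  expect_error(read_config(tmp), "nonsense_key")

  writeLines(c("threshold_A: 40", "threshold_B: 35"), tmp)
  expect_error(read_config(tmp), "threshold_A.*threshold_B")

  cfg <- model_config(s_mean = 12.5, seasonal = FALSE, sim_years = 7L)
  g <- grid_spec(s_mean_values = c(0, 10), replicates = 4, base_seed = 99,
                 scenarios = list(scenario_spec("redistribution", -5,
                                                start_year = 4L)))
  write_config(cfg, tmp, grid = g)
  back <- read_config(tmp)
  expect_equal(unclass(back$cfg), unclass(cfg))
  expect_equal(back$grid$s_mean_values, c(0, 10))
  expect_equal(back$grid$replicates, 4L)
  expect_equal(back$grid$scenarios[[1]]$kind, "redistribution")
  expect_equal(back$grid$scenarios[[1]]$delta, -5)
  expect_error(read_config(file.path(tempdir(), "absent.yaml")), "not found")
})

test_that("run and grid outputs are written deterministically", {
  cfg <- small_cfg(s_mean = 15, sim_years = 5L)
  run <- run_simulation(cfg, seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_run_result(run, d1)
  write_run_result(run, d2)
  for (f in c("monthly.csv", "breeders.csv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  js <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(js$seed, 8L)
  expect_match(js$config_digest, "^[0-9a-f]{8}$")

  g <- grid_spec(s_mean_values = c(5, 45), replicates = 2, base_seed = 4)
  gr <- run_grid(g, cfg)
  d3 <- withr::local_tempdir()
  write_grid_result(gr, d3)
  expect_true(all(file.exists(file.path(d3, c("grid_summary.csv",
                                              "finals.csv", "yearly.csv")))))
  # missing breeder means are empty fields, not zeros
  yearly <- utils::read.csv(file.path(d3, "yearly.csv"))
  if (any(yearly$n_breeders == 0)) {
    expect_true(all(is.na(
      yearly$mean_breeder_condition[yearly$n_breeders == 0])))
  }
})
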