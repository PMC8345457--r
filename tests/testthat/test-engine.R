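test_that("identical configuration and seed give bit-identical results", {
  fx <- figure_experiments(iterations = 2, base_seed = 5)$bromoxynil_1x1
  cfg <- fx$scenario
  cfg$horizon_days <- 120L
  a <- simulate_scenario(cfg, 1)
  b <- simulate_scenario(cfg, 1)
  expect_identical(a$nests[[1]]$abundance, b$nests[[1]]$abundance)
  expect_identical(a$nests[[1]]$total, b$nests[[1]]$total)
  # different iterations differ (stochastic model)
  c2 <- simulate_scenario(cfg, 2)
  expect_false(identical(a$nests[[1]]$total, c2$nests[[1]]$total))
})

test_that("control nests in a treated scenario match a pesticide-free run", {
  fx <- figure_experiments(iterations = 2, base_seed = 3)$dose_timing_15
  cfg <- fx$scenario
  cfg$horizon_days <- 240L
  treated <- simulate_scenario(cfg, 1)
  # same nests, no applications or profiles
  clean <- scenario_config(240, nests = cfg$nests, land = cfg$landscape,
                           iterations = 2, base_seed = 3, start_month = 12)
  control <- simulate_scenario(clean, 1)
  # nest1 is the untreated control: its trajectory is unaffected by the
  # presence of treatments elsewhere in the scenario
  expect_identical(treated$nests[["nest1"]]$abundance,
                   control$nests[["nest1"]]$abundance)
  # the highest-dose nest is affected
  expect_false(identical(treated$nests[["nest4"]]$total,
                         control$nests[["nest4"]]$total))
})

test_that("adding a nest does not perturb the draws of existing nests", {
  n1 <- rabbit_nest("alpha")
  n2 <- rabbit_nest("beta")
  cfg1 <- scenario_config(120, nests = list(n1), iterations = 2, base_seed = 9,
                          start_month = 12)
  cfg2 <- scenario_config(120, nests = list(n1, n2), iterations = 2,
                          base_seed = 9, start_month = 12)
  r1 <- simulate_scenario(cfg1, 1)
  r2 <- simulate_scenario(cfg2, 1)
  expect_identical(r1$nests[["alpha"]]$total, r2$nests[["alpha"]]$total)
})

test_that("replication summaries have coherent bounds and pool across nests", {
  fx <- rabbit_default(horizon_days = 150, iterations = 8, base_seed = 2)
  s <- replicate_scenario(fx$scenario)
  expect_true(all(s$table$low <= s$table$mean + 1e-9))
  expect_true(all(s$table$mean <= s$table$high + 1e-9))
  expect_equal(nrow(s$pooled), 151)
  # min/max mode bounds every stored replicate trajectory
  cfg <- fx$scenario
  cfg$summary_mode <- "min_max"
  s2 <- replicate_scenario(cfg)
  reps <- s2$replicates[[1]]
  nest_tab <- s2$table[s2$table$nest_id == names(s2$replicates)[1], ]
  expect_true(all(reps >= nest_tab$low))
  expect_true(all(reps <= nest_tab$high))
})

test_that("a deterministic degenerate scenario yields zero-width intervals", {
  ag <- two_groups(m = c(0, 0), r = c(0, 2))
  nest <- nest_config("d", species = "test", age_groups = ag,
                      initial_counts = c(3, 4), reproductive_season = 6L)
  cfg <- scenario_config(90, nests = list(nest), iterations = 3,
                         base_seed = 1, start_month = 12)
  s <- replicate_scenario(cfg)
  expect_true(all(s$table$high - s$table$low == 0))
  expect_true(all(s$table$mean == 7))
})

test_that("scenario validation lists all violations instead of failing fast", {
  cfg <- rabbit_default(horizon_days = 100, iterations = 2)$scenario
  bad <- unclass(cfg)
  bad$horizon_days <- 0L
  bad$iterations <- 1L
  probs <- validate_scenario(bad)
  expect_gte(length(probs), 2)
  expect_true(any(grepl("horizon", probs)))
  expect_true(any(grepl("iterations", probs)))
  # application on an unknown field is caught
  expect_error(scenario_config(100, nests = list(rabbit_nest()),
                               applications = list(
                                 application_event("px", "ghost", 5, 1)),
                               residue_params = list(
                                 residue_parameters("px", "crop", 50, 5)),
                               intake = intake_parameters("rabbit", 0.45),
                               profiles = list(bromoxynil_profile()),
                               iterations = 2),
               "unknown field")
})

test_that("exported tables round-trip and have the documented dimensions", {
  fx <- figure_experiments(iterations = 2, base_seed = 1)$bromoxynil_1x1
  cfg <- fx$scenario
  cfg$horizon_days <- 90L
  res <- simulate_scenario(cfg, 1)
  dir <- withr::local_tempdir()
  paths <- export_results(res, dir)
  ab <- utils::read.csv(file.path(dir, "abundance.csv"))
  expect_equal(nrow(ab), 90 * length(cfg$nests))
  expect_equal(ab$total, res$nests[[1]]$total[-1])
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$base_seed, cfg$base_seed)
  expect_equal(meta$iterations, cfg$iterations)
  expo <- utils::read.csv(file.path(dir, "exposure.csv"))
  expect_equal(nrow(expo), 90)
  # summary export round-trips exactly
  s <- replicate_scenario(cfg)
  export_results(s, dir)
  tab <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(tab$mean, s$table$mean)
})
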