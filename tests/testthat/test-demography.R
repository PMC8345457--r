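test_that("nest initialization fills groups as configured, deterministically", {
  ag <- rabbit_age_groups()
  cfg <- nest_config("n1", species = "rabbit", age_groups = ag,
                     initial_counts = c(20, 30, 40, 50),
                     reproductive_season = rabbit_season())
  st <- initialize_nest(cfg, 42)
  expect_equal(length(st$age), 140)
  expect_equal(group_counts(st, ag), c(20, 30, 40, 50))
  audit_population(st, ag)
  # same seed, same config -> identical state
  st2 <- initialize_nest(cfg, 42)
  expect_identical(st, st2)
  # degenerate sex ratio: only males, only the last group
  cfg2 <- nest_config("n2", species = "rabbit", age_groups = ag,
                      initial_counts = c(0, 0, 0, 10), sex_ratio_male = 1,
                      reproductive_season = rabbit_season())
  st3 <- initialize_nest(cfg2, 1)
  expect_equal(length(st3$age), 10)
  expect_true(all(st3$sex == "M"))
  expect_true(all(group_membership(st3, ag) == 4))
  expect_error(nest_config("n3", age_groups = ag,
                           initial_counts = c(-1, 0, 0, 10),
                           reproductive_season = 1), "negative")
})

test_that("monthly-to-daily conversion compounds back to the monthly rate", {
  expect_equal(monthly_to_daily_mortality(0, 30), 0)
  expect_equal(monthly_to_daily_mortality(1, 30), 1)
  # closed form 1 - 0.89^(1/30)
  expect_equal(monthly_to_daily_mortality(0.11, 30), 0.003877, tolerance = 1e-4)
  # compounding identity, to numerical precision
  for (m in c(0.05, 0.11, 0.38, 0.77, 0.99)) {
    d <- monthly_to_daily_mortality(m, 30)
    expect_equal(1 - (1 - d)^30, m, tolerance = 1e-12)
  }
  expect_error(monthly_to_daily_mortality(1.5), "\\[0, 1\\]")
  # engine's uniform conversion spreads the rate arithmetically
  expect_equal(daily_rate_from_monthly(0.11, 30, "uniform"), 0.11 / 30)
  expect_equal(daily_rate_from_monthly(0.11, 30, "compound"),
               monthly_to_daily_mortality(0.11, 30))
})

test_that("daily mortality is binomial per group with uniform allocation", {
  ag <- two_groups()
  st <- initialize_nest(tiny_nest(counts = c(500, 500)), 1)
  # zero rates leave the state unchanged
  out <- daily_mortality_step(st, c(0, 0), ag)
  expect_identical(out$state$age, st$age)
  expect_equal(out$deaths, c(0L, 0L))
  # rate one removes everyone
  out <- daily_mortality_step(st, c(1, 1), ag)
  expect_equal(length(out$state$age), 0)
  expect_equal(sum(out$deaths), 1000)
  # binomial expectation: 1000 individuals at rate 0.0039 -> ~3.9 mean deaths
  big <- initialize_nest(tiny_nest(counts = c(1000, 0)), 7)
  set.seed(99)
  deaths <- replicate(500, sum(daily_mortality_step(big, c(0.0039, 0), ag)$deaths))
  expect_equal(mean(deaths), 1000 * 0.0039, tolerance = 0.1)
  expect_error(daily_mortality_step(st, c(0.5, 1.2), ag), "\\[0, 1\\]")
})

test_that("daily reproduction is Poisson per female with the monthly mean spread over days", {
  ag <- two_groups(r = c(0, 4))
  # 200 individuals in the reproductive group, forced all-female
  cfg <- tiny_nest(counts = c(0, 200), sex_ratio_male = 0)
  st <- initialize_nest(cfg, 3)
  # out of season: no births
  out <- daily_reproduction_step(st, c(0, 4), in_season = FALSE,
                                 age_groups = ag)
  expect_equal(out$births, 0L)
  # zero rate: no births even in season
  out <- daily_reproduction_step(st, c(0, 0), in_season = TRUE, age_groups = ag)
  expect_equal(out$births, 0L)
  # Poisson mean: 200 females * 4 / 30 per day
  set.seed(11)
  births <- replicate(500,
    daily_reproduction_step(st, c(0, 4), TRUE, 30, ag)$births)
  expect_equal(mean(births), 200 * 4 / 30, tolerance = 0.8)
  # newborns enter group 0 at age 0 with fresh unique ids
  set.seed(12)
  out <- daily_reproduction_step(st, c(0, 4), TRUE, 30, ag)
  expect_gt(out$births, 0)
  newborn <- out$state$age == 0
  expect_equal(sum(newborn), out$births)
  audit_population(out$state, ag)
  expect_error(daily_reproduction_step(st, c(0, -4), TRUE, 30, ag), ">= 0")
})

test_that("ageing promotes individuals exactly at the group thresholds", {
  ag <- rabbit_age_groups()
  st <- new_state <- initialize_nest(
    nest_config("n", species = "rabbit", age_groups = ag,
                initial_counts = c(1, 0, 0, 0),
                reproductive_season = rabbit_season()), 5)
  st$age <- 29L  # one day below the group-1 threshold
  expect_equal(group_membership(st, ag), 1)
  st <- advance_age(st, ag)
  expect_equal(st$age, 30L)
  expect_equal(group_membership(st, ag), 2)
  # an old adult stays in the last group
  st$age <- 5000L
  expect_equal(group_membership(advance_age(st, ag), ag), 4)
  # composition: n applications raise ages by n
  st$age <- 0L
  for (i in 1:25) st <- advance_age(st, ag)
  expect_equal(st$age, 25L)
  expect_equal(st$day, 26L)
})

test_that("population is conserved daily: n(t+1) = n(t) - deaths + births", {
  fx <- rabbit_default(horizon_days = 120, iterations = 2)
  res <- simulate_scenario(fx$scenario, 1)
  n <- res$nests[[1]]
  expect_equal(diff(n$total), n$births - n$deaths)
  expect_true(all(n$abundance >= 0))
})

test_that("with zero mortality and out-of-season months abundance stays flat", {
  ag <- two_groups(m = c(0, 0), r = c(0, 2))
  # season is June only; a December start simulated for 150 days never reaches it
  nest <- nest_config("flat", species = "test", age_groups = ag,
                      initial_counts = c(10, 20), reproductive_season = 6L)
  cfg <- scenario_config(150, nests = list(nest), iterations = 1,
                         summary_mode = "min_max", start_month = 12)
  res <- simulate_scenario(cfg, 1)
  expect_true(all(res$nests[[1]]$total == 30))
})
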