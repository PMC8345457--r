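test_that("residues decay first-order and superpose across applications", {
  rp <- residue_parameters("px", "crop", rud = 1, dt50 = 10)
  one <- list(application_event("px", "f", 0, 1))
  expect_equal(residue_at(0, one, rp), 1)          # day of application
  expect_equal(residue_at(10, one, rp), 0.5)       # one half-life
  expect_equal(residue_at(c(0, 5), one, rp), c(1, 2^-0.5))
  # before the first application: zero
  late <- list(application_event("px", "f", 20, 1))
  expect_equal(residue_at(5, late, rp), 0)
  # superposition of two identical applications
  two <- list(application_event("px", "f", 0, 1),
              application_event("px", "f", 10, 1))
  expect_equal(residue_at(10, two, rp), 1.5)
  # exact half-life ratio after the last application
  r <- residue_at(c(30, 40), two, rp)
  expect_equal(r[2] / r[1], 0.5, tolerance = 1e-12)
  # monotone decay after the last application
  tail <- residue_at(10:60, two, rp)
  expect_true(all(diff(tail) < 0))
  # linearity: doubling the rate doubles the residue
  two2 <- list(application_event("px", "f", 0, 2),
               application_event("px", "f", 10, 2))
  expect_equal(residue_at(0:40, two2, rp), 2 * residue_at(0:40, two, rp))
  # drift fractions scale deposition by zone
  drift <- list(application_event("px", "f", 0, 1,
                                  drift_fractions = c(outer = 0.1)))
  expect_equal(residue_at(0, drift, rp, zone = "outer"), 0.1)
  expect_equal(residue_at(0, drift, rp, zone = "background"), 0)
  expect_error(residue_at(0, drift, rp, zone = "moon"), "zone")
})

test_that("daily dietary exposure weights residues by diet fraction and intake", {
  intake <- intake_parameters("rabbit", 0.5)
  d1 <- data.frame(zone = "a", food_item = "x", fraction = 1)
  expect_equal(daily_ete(d1, 10, intake), 5)
  d2 <- data.frame(zone = c("a", "b"), food_item = c("x", "y"),
                   fraction = c(0.5, 0.5))
  expect_equal(daily_ete(d2, c(10, 0), intake), 2.5)
  expect_equal(daily_ete(d2, c(0, 0), intake), 0)
})

test_that("time-weighted averages truncate at the simulation start", {
  cs <- const_series(3, 40)
  expect_equal(twa(cs, 12, 25), 3)          # constant series
  expect_equal(twa(cs, 1, 7), cs$ete[8])    # window 1 is the daily series
  expect_equal(twa(cs, 12, 0), cs$ete[1])   # truncated at day 0
  spike <- exposure_series("n", "px", c(rep(0, 20), 12, rep(0, 10)))
  expect_equal(twa(spike, 12, 20), 1)       # mean of 12 values, one of them 12
  # twa never exceeds the running maximum of the daily series
  decay <- exposure_series("n", "px", 10 * 2^(-(0:59) / 5))
  for (t in c(0, 3, 10, 30)) expect_lte(twa(decay, 7, t), max(decay$ete[1:(t + 1)]))
  expect_error(twa(cs, 0, 5), "window")
  expect_error(twa(cs, 5, 100), "horizon")
})

test_that("monthly maximum TWA matches a brute-force scan over the month", {
  app <- list(application_event("px", "f", 35, 2))
  rp <- residue_parameters("px", "crop", rud = 10, dt50 = 4)
  ete <- residue_at(0:89, app, rp) * 0.4
  s <- exposure_series("n", "px", ete)
  for (m in 0:2) {
    days <- (m * 30):(m * 30 + 29)
    expect_equal(max_monthly_twa(s, 5, m), max(twa(s, 5, days)))
  }
  expect_equal(max_monthly_twa(exposure_series("n", "px", rep(0, 60)), 5, 1), 0)
  expect_equal(max_monthly_twa(const_series(2, 60), 5, 1), 2)
  expect_error(max_monthly_twa(s, 5, -1), "month")
  expect_error(max_monthly_twa(s, 5, 9), "not simulated")
})

test_that("worst-case exposure equals intake times the treated-crop residue", {
  land <- landscape(list(rect_field("f1", 0, 0, 400, 400,
    crop_schedule = data.frame(crop = "cereal", start_day = 0, end_day = 999))))
  apps <- list(application_event("px", "f1", 10, 2))
  rps <- list(residue_parameters("px", "cereal", rud = 50, dt50 = 5))
  nest <- rabbit_nest("n1", location = c(200, 200), feeding_radius = 50)
  series <- build_exposure(nest, land, apps, rps,
                           intake_parameters("rabbit", 0.45), 60,
                           mode = "worst_case")
  expect_named(series, "px")
  expect_equal(series$px$ete, 0.45 * residue_at(0:59, apps, rps[[1]]))
  # landscape mode with the disc wholly inside the treated core agrees
  series_l <- build_exposure(nest, land, apps, rps,
                             intake_parameters("rabbit", 0.45), 60,
                             mode = "landscape")
  expect_equal(series_l$px$ete, series$px$ete, tolerance = 1e-9)
})

test_that("a nest outside the treated area receives no exposure in landscape mode", {
  land <- landscape(list(rect_field("f1", 0, 0, 400, 400,
    crop_schedule = data.frame(crop = "cereal", start_day = 0, end_day = 999))))
  apps <- list(application_event("px", "f1", 10, 2))
  rps <- list(residue_parameters("px", "cereal", rud = 50, dt50 = 5))
  far <- rabbit_nest("n2", location = c(5000, 5000), feeding_radius = 50)
  series <- build_exposure(far, land, apps, rps,
                           intake_parameters("rabbit", 0.45), 60,
                           mode = "landscape")
  expect_true(all(series$px$ete == 0))
})
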