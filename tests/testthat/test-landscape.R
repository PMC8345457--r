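test_that("rectangular fields partition into analytic ring areas", {
  f <- rect_field("f1", 0, 0, 100, 100, inner_band_width = 10,
                  outer_band_width = 5)
  zp <- zone_partition(f)
  expect_equal(zp$areas[["core"]], 80^2)
  expect_equal(zp$areas[["inner"]], 100^2 - 80^2)
  expect_equal(zp$areas[["outer"]], 110^2 - 100^2)
  # zero-width bands: core is the whole field
  f0 <- rect_field("f0", 0, 0, 100, 100)
  zp0 <- zone_partition(f0)
  expect_equal(zp0$areas[["core"]], 1e4)
  expect_equal(zp0$areas[["inner"]], 0)
  expect_equal(zp0$areas[["outer"]], 0)
  # determinism
  expect_identical(zone_partition(f)$areas, zone_partition(f)$areas)
  # degenerate band widths rejected with a clear message
  expect_error(zone_partition(rect_field("fb", 0, 0, 20, 20,
                                         inner_band_width = 10)),
               "no core")
})

test_that("non-rectangular fields are partitioned by distance to boundary", {
  tri <- field("tri", cbind(c(0, 200, 0), c(0, 0, 200)),
               inner_band_width = 10)
  zp <- zone_partition(tri, resolution = 1)
  total <- 200 * 200 / 2
  expect_equal(zp$areas[["core"]] + zp$areas[["inner"]], total,
               tolerance = 0.02)
  # eroding a right triangle with legs 200 by 10 leaves a similar triangle
  # with inradius reduced by 10: side scale (r - 10)/r
  r_in <- (200 + 200 - sqrt(2) * 200) / 2
  core_exact <- total * ((r_in - 10) / r_in)^2
  expect_equal(zp$areas[["core"]], core_exact, tolerance = 0.02)
  # zone classification is consistent with the areas
  expect_equal(zp$classify(40, 40), "core")      # deep inside
  expect_equal(zp$classify(2, 2), "inner")
  expect_true(is.na(zp$classify(300, 300)))
})

test_that("feeding-area overlap fractions are exhaustive and match geometry", {
  land <- landscape(list(rect_field("f1", 0, 0, 1000, 1000)))
  # disc wholly inside the field core
  inside <- feeding_zone_overlap(feeding_area("n", c(500, 500), 50), land)
  expect_equal(unname(inside["f1:core"]), 1)
  # disc wholly outside all fields
  out <- feeding_zone_overlap(feeding_area("n", c(5000, 5000), 50), land)
  expect_equal(unname(out["background"]), 1)
  # disc centered on a straight edge of a very large field: half in, half out
  edge <- feeding_zone_overlap(feeding_area("n", c(0, 500), 50), land)
  expect_equal(unname(edge["f1:core"]), 0.5, tolerance = 0.02)
  expect_equal(sum(edge), 1, tolerance = 1e-9)
  # fractions always sum to one
  mid <- feeding_zone_overlap(feeding_area("n", c(980, 500), 60), land)
  expect_equal(sum(mid), 1, tolerance = 1e-9)
  expect_error(feeding_zone_overlap(feeding_area("n", c(0, 0), 10), land,
                                    resolution = 20), "resolution")
})

test_that("halving the raster resolution changes fractions within the stated bound", {
  land <- landscape(list(rect_field("f1", 0, 0, 1000, 1000)))
  area <- feeding_area("n", c(30, 500), 50)  # straddles the boundary
  f1 <- feeding_zone_overlap(area, land, resolution = 1)
  f2 <- feeding_zone_overlap(area, land, resolution = 0.5)
  expect_lt(abs(f1["f1:core"] - f2["f1:core"]), 2 * 1 / 50)
})

test_that("overlapping fields resolve by declaration order", {
  land <- landscape(list(rect_field("first", 0, 0, 100, 100),
                         rect_field("second", 50, 0, 150, 100)))
  fr <- feeding_zone_overlap(feeding_area("n", c(75, 50), 10), land)
  expect_equal(unname(fr["first:core"]), 1)
})

test_that("diet fractions weight zone areas by food availability", {
  # single zone, single item
  d <- diet_fractions(c(a = 1),
                      data.frame(zone = "a", food_item = "x", weight = 2))
  expect_equal(d$fraction, 1)
  # equal areas, equal weights -> symmetric split
  d <- diet_fractions(c(a = 0.5, b = 0.5),
                      data.frame(zone = c("a", "b"), food_item = c("x", "y"),
                                 weight = c(1, 1)))
  expect_equal(sort(d$fraction), c(0.5, 0.5))
  # areas 0.75/0.25 with weights 1/2 -> 0.6/0.4
  d <- diet_fractions(c(a = 0.75, b = 0.25),
                      data.frame(zone = c("a", "b"), food_item = c("x", "y"),
                                 weight = c(1, 2)))
  expect_equal(d$fraction, c(0.6, 0.4))
  expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
  # invariance to uniform weight rescaling
  d2 <- diet_fractions(c(a = 0.75, b = 0.25),
                       data.frame(zone = c("a", "b"), food_item = c("x", "y"),
                                  weight = c(10, 20)))
  expect_equal(d$fraction, d2$fraction)
  expect_error(diet_fractions(c(a = 1),
                              data.frame(zone = "a", food_item = "x",
                                         weight = 0)),
               "no food")
})

test_that("zone areas are translation invariant", {
  for (off in list(c(0, 0), c(1234, -777))) {
    f <- rect_field("f", off[1], off[2], off[1] + 100, off[2] + 100,
                    inner_band_width = 10, outer_band_width = 5)
    expect_equal(zone_partition(f)$areas, c(core = 6400, inner = 3600,
                                            outer = 2100))
  }
})
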