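test_that("a circle of radius 10 has truth diameter 20 and area ~pi*100", {
  sim <- make_mask(64, 64, list(shape_ellipse(c(32, 32), 10, 10)))
  expect_equal(sim$truth$true_diameter_px, 20)
  expect_equal(sim$truth$true_area_px, pi * 100)
})

test_that("two disjoint squares give truth count 2 and measured count 2", {
  sq1 <- shape_polygon(rbind(c(10, 10), c(10, 20), c(20, 20), c(20, 10)))
  sq2 <- shape_polygon(rbind(c(40, 40), c(40, 52), c(52, 52), c(52, 40)))
  sim <- make_mask(64, 64, list(sq1, sq2))
  expect_equal(nrow(sim$truth), 2)
  expect_equal(nrow(measure_mask(sim$mask, min_area_px = 0)), 2)
})

test_that("polygon truth uses vertex-pair distance and shoelace area", {
  tri <- shape_polygon(rbind(c(10, 10), c(10, 30), c(25, 10)))
  sim <- make_mask(40, 40, list(tri))
  expect_equal(sim$truth$true_diameter_px, 25) # 3-4-5 triangle hypotenuse
  expect_equal(sim$truth$true_area_px, 20 * 15 / 2)
})

test_that("generators are pure functions of parameters and seed", {
  a <- make_mask(64, 64, list(shape_blob(c(32, 32), 14, seed = 2)),
                 speckle_density = 0.01, hole_density = 0.02, seed = 9)
  b <- make_mask(64, 64, list(shape_blob(c(32, 32), 14, seed = 2)),
                 speckle_density = 0.01, hole_density = 0.02, seed = 9)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)
  expect_identical(make_calibration_pairs(seed = 4), make_calibration_pairs(seed = 4))
  expect_identical(make_cooling_curve(sigma = 0.3, seed = 4),
                   make_cooling_curve(sigma = 0.3, seed = 4))
  expect_identical(make_assay_tables(sigma = 0.01, seed = 4),
                   make_assay_tables(sigma = 0.01, seed = 4))
})

test_that("overlapping or out-of-frame shapes are rejected", {
  expect_error(
    make_mask(64, 64, list(shape_ellipse(c(30, 30), 10, 10),
                           shape_ellipse(c(30, 45), 10, 8))),
    "shapes overlap"
  )
  expect_error(
    make_mask(32, 32, list(shape_ellipse(c(16, 16), 20, 10))),
    "does not fit"
  )
})

test_that("noiseless calibration pairs lie exactly on the line", {
  p <- make_calibration_pairs(n = 38, slope = 0.12, intercept = 0.3, sigma = 0)
  expect_equal(p$y, 0.12 * p$x + 0.3, tolerance = 1e-12)
  expect_error(make_calibration_pairs(n = 1), "insufficient pairs")
})

test_that("fitted slopes over 100 seeds centre on the truth", {
  slopes <- vapply(1:100, function(s) {
    fit_linear(make_calibration_pairs(n = 38, sigma = 0.05, seed = s))$slope
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.12), 2 * se + 1e-6)
})

test_that("cooling curve obeys the closed form and approaches ambient", {
  tr <- make_cooling_curve(T_surr = 25, T_max = 55, tau_s = 120,
                           dt = 10, duration = 1200, sigma = 0)
  at_tau <- tr$temp_C[tr$time_s == 120]
  expect_equal(at_tau, 25 + 30 / exp(1), tolerance = 1e-12)
  expect_lt(abs(tr$temp_C[nrow(tr)] - 25), 30 * exp(-10) + 1e-6)
})

test_that("assay tables recover their embedded truths exactly at sigma 0", {
  tabs <- make_assay_tables(hemolysis_truth_pct = 50, sigma = 0, seed = 0)
  hr <- plate_rates(tabs$hemolysis, "hemolysis")
  expect_equal(hr$rate_pct, rep(50, 3), tolerance = 1e-12)
  curve <- fit_linear(tabs$fluorescence_curve, x_units = "mM", y_units = "AU")
  expect_equal(curve$slope, tabs$truth$fluor_slope, tolerance = 1e-9)
  expect_equal(curve$intercept, tabs$truth$fluor_intercept, tolerance = 1e-9)
  expect_equal(tabs$h2s_groups$concentration_mM, c(2.8, 2.5, 1.27, 0.98, 0.676))
})

test_that("end-to-end: ellipse masks recover diameter and count from truth", {
  withr::with_seed(42, {
    for (i in 1:10) {
      ang <- runif(1, 0, 180)
      ctr <- c(runif(1, 26, 38), runif(1, 26, 38))
      sim <- make_mask(64, 64, list(shape_ellipse(ctr, 20, 10, angle = ang)))
      rec <- measure_mask(sim$mask, min_area_px = 0)
      expect_equal(nrow(rec), 1)
      expect_lte(abs(rec$max_diameter_px - sim$truth$true_diameter_px), 1.5)
    }
  })
})

test_that("speckle is filtered by the default minimum area over many seeds", {
  for (s in 1:50) {
    sim <- make_mask(64, 64,
                     list(shape_ellipse(c(32, 32), 16, 9, angle = s * 7)),
                     speckle_density = 0.003, seed = s)
    rec <- measure_mask(sim$mask, min_area_px = 5)
    expect_equal(nrow(rec), nrow(sim$truth), info = paste("seed", s))
  }
})
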