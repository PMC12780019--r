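test_that("theta is 1 at the peak, 0 at ambient, 0.5 midway", {
  tr <- tibble::tibble(time_s = 0:2,
                       temp_C = c(55, (55 + 25) / 2, 25))
  th <- normalize_theta(tr, T_surr = 25, T_max = 55)
  expect_equal(th$theta, c(1, 0.5, 0))
  expect_equal(th$flagged, c(FALSE, FALSE, TRUE))
  expect_error(normalize_theta(tr, T_surr = 55, T_max = 25),
               "invalid temperature bounds")
})

test_that("noiseless cooling recovers tau to 1e-6 relative", {
  tr <- make_cooling_curve(T_surr = 25, T_max = 55, tau_s = 120,
                           dt = 1, duration = 600, sigma = 0)
  fit <- fit_time_constant(tr, T_surr = 25, T_max = 55)
  expect_equal(fit$tau_s, 120, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("noisy cooling recovers tau within 2% (median over 20 seeds)", {
  errs <- vapply(1:20, function(s) {
    tr <- make_cooling_curve(T_surr = 26.1, T_max = 53.5, tau_s = 120,
                             dt = 1, duration = 600, sigma = 0.2, seed = s)
    abs(fit_time_constant(tr, 26.1, 53.5)$tau_s - 120) / 120
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("tau recovery holds across a tau/noise grid", {
  # median relative error <= max(0.1%, 5 * sigma / (T_max - T_surr))
  for (tau in c(30, 60, 120, 300)) {
    for (sigma in c(0, 0.1, 0.5)) {
      errs <- vapply(1:11, function(s) {
        tr <- make_cooling_curve(T_surr = 26.1, T_max = 53.5, tau_s = tau,
                                 dt = tau / 60, duration = 5 * tau,
                                 sigma = sigma, seed = s)
        # high-noise traces legitimately trigger the non-monotone-theta warning
        fit <- suppressWarnings(fit_time_constant(tr, 26.1, 53.5))
        abs(fit$tau_s - tau) / tau
      }, numeric(1))
      bound <- max(0.001, 5 * sigma / (53.5 - 26.1))
      expect_lt(stats::median(errs), bound)
    }
  }
})

test_that("a constant-temperature trace is rejected as insufficient", {
  tr <- tibble::tibble(time_s = 0:10, temp_C = rep(53.5, 11))
  expect_error(fit_time_constant(tr, 26.1, 53.5), "insufficient cooling data")
})

test_that("constructed identity gives eta = 1 and equal bounds give eta = 0", {
  hs <- 600 * (1 - 10^(-1.31)) / (53.5 - 26.1) # makes numerator = denominator
  r1 <- conversion_efficiency(T_max = 53.5, T_surr = 26.1, A_808 = 1.31,
                              I = 600, hs = hs, Q_dis = 0)
  expect_equal(r1$eta, 1, tolerance = 1e-12)
  r0 <- conversion_efficiency(T_max = 26.1, T_surr = 26.1, A_808 = 1.31,
                              I = 600, hs = 4.9, Q_dis = 0)
  expect_equal(r0$eta, 0)
})

test_that("efficiency equals the hand-computed energy balance", {
  # independent arithmetic: hs = 0.3 g * 1.96 J/(g C) / 120 s = 4.9 mW/C
  expected <- (0.3 * 1.96 / 120 * 1000 * (53.5 - 26.1) - 30) /
    (600 * (1 - 10^(-1.31)))
  res <- conversion_efficiency(T_max = 53.5, T_surr = 26.1, A_808 = 1.31,
                               I = 600, m = 0.3, c = 1.96, tau_s = 120,
                               Q_dis = 30)
  expect_equal(res$hs, 4.9, tolerance = 1e-12)
  expect_equal(res$eta, expected, tolerance = 1e-12)
})

test_that("hs from (m, c, tau) and direct hs give identical eta", {
  a <- conversion_efficiency(53.5, 26.1, 1.31, 600,
                             m = 0.3, c = 1.96, tau_s = 120, Q_dis = 10)
  b <- conversion_efficiency(53.5, 26.1, 1.31, 600, hs = 4.9, Q_dis = 10)
  expect_equal(a$eta, b$eta, tolerance = 1e-12)
})

test_that("eta is monotone: increasing in T_max, decreasing in Q_dis and I", {
  base <- function(T_max = 50, Q_dis = 10, I = 600) {
    conversion_efficiency(T_max, 26.1, 1.31, I, hs = 4.9, Q_dis = Q_dis)$eta
  }
  t_grid <- vapply(seq(30, 60, by = 5), function(t) base(T_max = t), numeric(1))
  expect_true(all(diff(t_grid) > 0))
  q_grid <- vapply(seq(0, 60, by = 10), function(q) base(Q_dis = q), numeric(1))
  expect_true(all(diff(q_grid) < 0))
  i_grid <- vapply(seq(400, 1000, by = 100), function(i) base(I = i), numeric(1))
  expect_true(all(diff(i_grid) < 0))
  # limit: eta -> 0 as T_max -> T_surr with Q_dis = 0
  eps_eta <- vapply(26.1 + c(1, 0.1, 0.01), function(t) {
    conversion_efficiency(t, 26.1, 1.31, 600, hs = 4.9, Q_dis = 0)$eta
  }, numeric(1))
  expect_true(all(diff(eps_eta) < 0) && eps_eta[3] < 1e-4)
})

test_that("out-of-range efficiency is reported with a warning flag", {
  expect_warning(
    res <- conversion_efficiency(90, 26.1, 1.31, 100, hs = 4.9, Q_dis = 0),
    "outside"
  )
  expect_true(res$warning_flag)
  expect_gt(res$eta, 1)
})

test_that("invalid optical parameters are rejected", {
  expect_error(conversion_efficiency(53.5, 26.1, 1.31, 0, hs = 4.9),
               "invalid optical parameters")
  expect_error(conversion_efficiency(53.5, 26.1, -1, 600, hs = 4.9),
               "invalid optical parameters")
})

test_that("exact exponential samples give tau = 2 and half-life 2 ln 2", {
  s <- data.frame(time = 0:5, value = 10 * exp(-(0:5) / 2))
  fit <- fit_exponential_decay(s, baseline = 0)
  expect_equal(fit$tau, 2, tolerance = 1e-12)
  expect_equal(fit$half_life, 2 * log(2), tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("decay fit equals the closed-form log-linear OLS solution", {
  withr::with_seed(11, {
    t <- seq(0, 12, by = 1.5)
    v <- 50 * exp(-t / 4.56)
    fit <- fit_exponential_decay(data.frame(time = t, value = v))
    z <- log(v)
    slope <- sum((t - mean(t)) * (z - mean(z))) / sum((t - mean(t))^2)
    expect_equal(fit$tau, -1 / slope, tolerance = 1e-12)
  })
})

test_that("noisy decay recovers a 3.16 h half-life within 5% (median of 20 seeds)", {
  errs <- vapply(1:20, function(s) {
    d <- make_decay_curve(v0 = 100, half_life = 3.16,
                          times = seq(0, 12, by = 1), sigma_rel = 0.05,
                          seed = s + 8)
    abs(fit_exponential_decay(d)$half_life - 3.16) / 3.16
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("all-baseline samples are rejected", {
  expect_error(
    fit_exponential_decay(data.frame(time = 0:5, value = rep(2, 6)),
                          baseline = 2),
    "insufficient decay data"
  )
})

test_that("delta_T interpolates the temperature rise", {
  flat <- tibble::tibble(time_s = c(0, 100, 200), temp_C = rep(30, 3))
  expect_equal(delta_T(flat, 150), 0)
  ramp <- tibble::tibble(time_s = c(0, 300), temp_C = c(26.1, 48.6))
  expect_equal(delta_T(ramp, 300), 22.5)
  ramp2 <- tibble::tibble(time_s = c(0, 100), temp_C = c(20, 30))
  expect_equal(delta_T(ramp2, 50), 5)
  expect_error(delta_T(ramp2, 150), "time outside trace")
})

test_that("end-to-end efficiency from a trace carries fit provenance", {
  tr <- make_cooling_curve(T_surr = 26.1, T_max = 53.5, tau_s = 120, sigma = 0)
  res <- photothermal_efficiency(tr, T_surr = 26.1, T_max = 53.5,
                                 A_808 = 1.31, I = 600, m = 0.3, c = 1.96)
  expect_equal(res$hs, 4.9, tolerance = 1e-4)
  expect_equal(res$theta_fit_r2, 1, tolerance = 1e-9)
  expect_gt(res$n_points_used, 100)
})
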