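test_that("haemolysis controls anchor the scale at 0% and 100%", {
  expect_equal(hemolysis_rate(1.0, 0.05, 1.0), 100)
  expect_equal(hemolysis_rate(0.05, 0.05, 1.0), 0)
  expect_equal(hemolysis_rate((1.0 + 0.05) / 2, 0.05, 1.0), 50)
  expect_error(hemolysis_rate(0.5, 0.3, 0.3), "degenerate controls")
  expect_warning(hemolysis_rate(1.2, 0.05, 1.0), "outside")
})

test_that("viability controls anchor 0% and 100%; OD triple gives 87.8%", {
  expect_equal(cell_viability(1.1, 0.1, 1.1), 100)
  expect_equal(cell_viability(0.1, 0.1, 1.1), 0)
  # blank 0.1, control 1.1, experimental 0.978: (0.978-0.1)/(1.1-0.1)*100
  expect_equal(cell_viability(0.978, 0.1, 1.1), 87.8)
})

test_that("mass fractions reproduce the reported composition", {
  expect_equal(mass_fraction(0.8076, 4.75), 17.00)
  expect_equal(mass_fraction(0.152, 4.75), 3.20)
  expect_equal(mass_fraction(0, 3), 0)
  expect_error(mass_fraction(1, 0), "invalid total")
})

test_that("reduction rate matches the reported H2S depletion statistics", {
  expect_equal(signif(reduction_rate(2.8, 1.27), 3), 54.6)
  expect_equal(reduction_rate(2.8, 0.676), 75.857, tolerance = 1e-4)
  expect_equal(reduction_rate(1.5, 1.5), 0)
  expect_error(reduction_rate(0, 1), "zero control")
})

test_that("reduction rate is bounded and antitone in the treated concentration", {
  withr::with_seed(20, {
    ctrl <- runif(200, 0.5, 5)
    trt <- runif(200) * ctrl
    r <- reduction_rate(ctrl, trt)
    expect_true(all(r >= 0 & r <= 100))
  })
  treated <- seq(0, 2.8, by = 0.2)
  r <- reduction_rate(2.8, treated)
  expect_true(all(diff(r) < 0))
})

test_that("organ and tumour indices are weight ratios in percent", {
  expect_equal(organ_index(0.2, 20), 1.0)
  expect_equal(organ_index(0, 20), 0)
  expect_equal(tumour_index(1.0, 20), 5.0)
  expect_error(organ_index(0.2, 0), "body_weight")
})

test_that("apoptosis totals reproduce the reported flow-cytometry sums", {
  expect_equal(apoptosis_total(27.0, 14.5, 23), 64.5)
  expect_equal(apoptosis_total(0, 0, 0), 0)
  # commutative in its three quadrant arguments
  expect_equal(apoptosis_total(14.5, 23, 27.0), apoptosis_total(27.0, 14.5, 23))
  expect_error(apoptosis_total(-1, 10, 10), "\\[0, 100\\]")
})

test_that("formula operations agree with one-line oracles on random inputs", {
  withr::with_seed(21, {
    n <- 1000
    s <- runif(n, 0, 2); neg <- runif(n, 0, 0.2); pos <- runif(n, 0.5, 2.5)
    expect_equal(suppressWarnings(hemolysis_rate(s, neg, pos)),
                 (s - neg) / (pos - neg) * 100, tolerance = 1e-12)
    expect_equal(suppressWarnings(cell_viability(s, neg, pos)),
                 (s - neg) / (pos - neg) * 100, tolerance = 1e-12)
    comp <- runif(n, 0, 5); tot <- runif(n, 5, 10)
    expect_equal(mass_fraction(comp, tot, digits = Inf),
                 comp / tot * 100, tolerance = 1e-12)
    ctrl <- runif(n, 0.1, 5); trt <- runif(n, 0, 5)
    expect_equal(reduction_rate(ctrl, trt),
                 (ctrl - trt) / ctrl * 100, tolerance = 1e-12)
    ow <- runif(n, 0, 2); bw <- runif(n, 15, 30)
    expect_equal(organ_index(ow, bw), ow / bw * 100, tolerance = 1e-12)
    e <- runif(n, 0, 33); l <- runif(n, 0, 33); nec <- runif(n, 0, 33)
    expect_equal(apoptosis_total(e, l, nec), e + l + nec, tolerance = 1e-12)
  })
})

test_that("haemolysis and viability are affine in the sample OD", {
  # two-point linearity: value at the midpoint equals the mean of endpoints
  lo <- hemolysis_rate(0.2, 0.05, 1.0)
  hi <- hemolysis_rate(0.9, 0.05, 1.0)
  expect_equal(hemolysis_rate(0.55, 0.05, 1.0), (lo + hi) / 2, tolerance = 1e-12)
  lo <- cell_viability(0.3, 0.1, 1.1)
  hi <- cell_viability(1.0, 0.1, 1.1)
  expect_equal(cell_viability(0.65, 0.1, 1.1), (lo + hi) / 2, tolerance = 1e-12)
})

test_that("H2S quantification inverts the standard curve and floors negatives", {
  ident <- fit_linear(data.frame(x = c(0, 1, 2, 3), y = c(0, 1, 2, 3)))
  out <- quantify_h2s(data.frame(group = "PBS", fluorescence = 2.8), ident)
  expect_equal(out$concentration, 2.8)

  curve <- fit_linear(data.frame(x = c(0, 1, 2, 3, 4),
                                 y = 50 + 100 * c(0, 1, 2, 3, 4)),
                      x_units = "mM", y_units = "AU")
  out2 <- quantify_h2s(data.frame(group = "MCC", fluorescence = 330), curve)
  expect_equal(out2$concentration, 2.8, tolerance = 1e-12)

  expect_warning(
    out3 <- quantify_h2s(data.frame(group = "x", fluorescence = 10), curve),
    "floored"
  )
  expect_equal(out3$concentration, 0)
  expect_true(out3$floored)
})

test_that("the bundled group fixture reproduces the depletion statistics", {
  tab <- reduction_table(h2s_tumour_groups(), control = "PBS")
  expect_equal(signif(tab$reduction_pct[tab$group == "MCC"], 3), 54.6)
  expect_equal(tab$reduction_pct[tab$group == "PfCC+NIR"], 75.857,
               tolerance = 1e-4)
  expect_equal(tab$reduction_pct[tab$group == "PBS"], 0)
})

test_that("plate tables produce per-well rates via the control wells", {
  tabs <- make_assay_tables(hemolysis_truth_pct = 50, seed = 3)
  hr <- plate_rates(tabs$hemolysis, "hemolysis")
  expect_equal(hr$rate_pct, rep(50, 3), tolerance = 1e-12)
  vr <- plate_rates(tabs$viability, "viability")
  expect_equal(vr$rate_pct, rep(87.8, 3), tolerance = 1e-12)
  expect_error(plate_rates(data.frame(well = "A1", role = "weird", od = 1)),
               "unknown role")
})
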