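# Susceptibility extraction calculus and linear calibrations.

test_that("mixture reference is the fraction-weighted mean", {
  expect_equal(mixture_chi(solvent_97d2o()),
               0.97 * -9.01 + 0.03 * -9.05)
  expect_equal(mixture_chi(solvent_97d2o()), -9.0112)
  expect_equal(mixture_chi(solvent_99d2o()), -9.0104)
  expect_equal(mixture_chi(data.frame(fraction = 1, chi = -9.4)), -9.4)
  expect_error(mixture_chi(data.frame(fraction = c(0.5, 0.4),
                                      chi = c(-9, -9))), "sum to 1")
  expect_error(mixture_chi(data.frame(fraction = c(1.5, -0.5),
                                      chi = c(-9, -9))), "non-negative")
})

test_that("interface 2x rule recovers the printed solid susceptibilities", {
  # printed resin: -0.195 ppm against 99% D2O
  expect_equal(round(chi_from_interface_shift(-0.195, -9.0104), 2), -9.40)
  # matched glass: -0.032 ppm against 97% D2O
  expect_equal(round(chi_from_interface_shift(-0.032, -9.0112), 2), -9.08)
  expect_equal(chi_from_interface_shift(-0.032, -9.0112), -9.0752)
  # matched media
  expect_equal(chi_from_interface_shift(0, -9.01), -9.01)
  # affine: doubling delta doubles the contrast
  d1 <- chi_from_interface_shift(-0.1, -9) - (-9)
  d2 <- chi_from_interface_shift(-0.2, -9) - (-9)
  expect_equal(d2, 2 * d1)
})

test_that("isotope difference applies the protonation-span correction", {
  expect_equal(isotope_chi_difference(0.0183, 0.94), 2 * 0.0183 / 0.94)
  expect_equal(round(isotope_chi_difference(0.0183, 0.94), 2), 0.04)
  expect_equal(isotope_chi_difference(0.5, 1), 1)
  expect_equal(isotope_chi_difference(0, 0.94), 0)
  expect_error(isotope_chi_difference(0.1, 0), "fraction_span")
})

test_that("salt model evaluates the calibrated line", {
  expect_equal(salt_chi(2, "H2O"), -8.65)
  expect_equal(salt_chi(0, "D2O"), -9.01)
  expect_equal(salt_chi(1, "D2O"), -8.81)
  # the two intercepts differ by the isotope difference by construction
  expect_equal(salt_chi(0, "H2O") - salt_chi(0, "D2O"), -0.04)
  expect_error(salt_chi(-0.1), "non-negative")
  expect_warning(salt_chi(3, "D2O"), "extrapolating")
})

test_that("hz/ppm conversion uses the spectrometer frequency", {
  expect_equal(hz_to_ppm(117, 600.13), 117 / 600.13)
  expect_equal(round(hz_to_ppm(117, 600.13), 3), 0.195)
  expect_equal(hz_to_ppm(0), 0)
  expect_equal(hz_to_ppm(800, 800), 1)
  expect_equal(ppm_to_hz(hz_to_ppm(53.7, 600.13), 600.13), 53.7)
})

test_that("fit_linear matches the normal-equations oracle", {
  # exact line: zero residuals
  d <- data.frame(x = c(0, 0.5, 1, 1.5, 2))
  d$y <- 0.2 * d$x - 9.01
  cal <- fit_linear(d, x, y)
  expect_equal(cal$slope, 0.2)
  expect_equal(cal$intercept, -9.01)
  expect_lt(max(abs(cal$residuals)), 1e-12)
  # two points: the interpolating line
  cal2 <- fit_linear(data.frame(x = c(0, 5), y = c(117, -80)), x, y)
  expect_equal(cal2$slope, (-80 - 117) / 5)
  expect_equal(cal2$intercept, 117)
  # random small inputs against the brute-force oracle
  for (seed in 1:10) {
    dd <- withr::with_seed(seed, data.frame(x = stats::runif(7, 0, 2),
                                            y = stats::rnorm(7)))
    ref <- ols_normal_equations(dd$x, dd$y)
    cc <- fit_linear(dd, x, y)
    expect_equal(cc$intercept, unname(ref["intercept"]), tolerance = 1e-10)
    expect_equal(cc$slope, unname(ref["slope"]), tolerance = 1e-10)
  }
  expect_error(fit_linear(data.frame(x = 1, y = 1), x, y), "2 points")
  expect_error(fit_linear(data.frame(x = c(1, 1), y = 1:2), x, y),
               "degenerate")
})

test_that("tidy and glance summarize a calibration", {
  d <- generate_synthetic_series(0.2, -9.01, c(0, 0.5, 1, 1.5, 2),
                                 noise_sd = 0.01, seed = 3)
  cal <- fit_linear(d, x, y)
  td <- tidy(cal)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], cal$slope)
  gl <- glance(cal)
  expect_equal(gl$nobs, 5)
  expect_gt(gl$r.squared, 0.99)
  expect_equal(predict(cal, 1), cal$intercept + cal$slope)
})

test_that("synthetic salt series recover the calibrated slope", {
  # quick screen; the full 1000-seed study runs with the acceptance suite
  slopes <- vapply(1:200, function(s) {
    d <- generate_synthetic_series(0.2, -9.01, c(0, 0.5, 1, 1.5, 2),
                                   noise_sd = 0.01, seed = s)
    fit_linear(d, x, y)$slope
  }, numeric(1))
  expect_gte(mean(abs(slopes - 0.2) <= 0.03), 0.95)
})

test_that("doping zero crossing interpolates the printed endpoints", {
  x0 <- doping_zero_crossing(data.frame(c = c(0, 5), s = c(117, -80)), c, s)
  expect_equal(as.numeric(x0), 117 * 5 / 197, tolerance = 1e-12)
  expect_equal(round(as.numeric(x0), 2), 2.97)
  expect_false(attr(x0, "extrapolated"))
  expect_equal(as.numeric(
    doping_zero_crossing(data.frame(c = c(0, 5), s = c(0, -80)), c, s)), 0)
  expect_error(doping_zero_crossing(data.frame(c = 1, s = 5), c, s))
  expect_warning(
    x1 <- doping_zero_crossing(data.frame(c = c(0, 5), s = c(117, 20)), c, s),
    "extrapolated")
  expect_true(attr(x1, "extrapolated"))
})

test_that("field simulation and extraction close the loop on chi_solid", {
  # simulate the matched-tube geometry for a known glass chi, read off the
  # near-interface and far offsets, and invert with the 2x rule
  chi_s <- -9.011
  chi_g <- -9.075
  sc <- preset_scene("shigemi", chi_solvent = chi_s, chi_solid = chi_g,
                     solvent_height = 25, solid_length = 6)
  g <- voxel_grid(c(48, 48, 320), 0.1, center = c(0, 0, 9))
  sim <- simulate_field(sc, g, shimmed = TRUE)
  near <- field_at(sim$field, cbind(0, 0, g$spacing[3] / 2))
  far <- field_at(sim$field, cbind(0, 0, 13))
  chi_hat <- chi_from_interface_shift(near - far, chi_s)
  expect_lt(abs(chi_hat - chi_g) / abs(chi_g - chi_s), 0.05)
})
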