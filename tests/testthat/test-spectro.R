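test_that("Lorentzian area matches numeric integration", {
  cmp <- lorentzian_component(amplitude = 2.4, center_ppm = -200, fwhm_Hz = 30)
  # integrate the amplitude-form lineshape over frequency (Hz)
  num <- integrate(function(nu) 2.4 / (1 + (2 * nu / 30)^2), -Inf, Inf)$value
  expect_equal(cmp$area, num, tolerance = 1e-6)
  expect_equal(cmp$area, 2.4 * 30 * pi / 2, tolerance = 1e-12)
})

test_that("three-component deconvolution round-trips a clean spectrum", {
  comps <- list(lorentzian_component(1.0, -199.7, 25),
                lorentzian_component(0.6, -200.9, 18),
                lorentzian_component(0.3, -201.0, 60))
  sp <- gen_spectrum(comps, c(-203.5, -197.5), 1024)
  d <- deconvolve_1d(sp, c(-199.7, -200.9, -201.0))
  o <- order(d$components$center_ppm, decreasing = TRUE)
  expect_equal(d$components$center_ppm[o], c(-199.7, -200.9, -201.0),
               tolerance = 1e-5)
  expect_equal(d$components$fwhm_Hz[o], c(25, 18, 60), tolerance = 1e-4)
  expect_equal(d$components$amplitude[o], c(1.0, 0.6, 0.3), tolerance = 1e-4)
  expect_equal(sum(d$populations), 1, tolerance = 1e-12)
})

test_that("deconvolved populations are invariant to intensity rescaling", {
  comps <- list(lorentzian_component(1.0, -199.7, 25),
                lorentzian_component(0.4, -200.9, 18))
  sp <- gen_spectrum(comps, c(-202.5, -198), 512)
  sp2 <- spectrum1d(sp$ppm, 2.7 * sp$intensity, sp$frequency_MHz)
  d1 <- deconvolve_1d(sp, c(-199.7, -200.9))
  d2 <- deconvolve_1d(sp2, c(-199.7, -200.9))
  expect_equal(unname(d1$populations), unname(d2$populations),
               tolerance = 1e-8)
})

test_that("noisy deconvolution recovers populations across replicates", {
  comps <- list(lorentzian_component(1.0, -199.7, 25),
                lorentzian_component(0.6, -200.9, 18),
                lorentzian_component(0.3, -201.0, 60))
  truth <- vapply(comps, function(x) x$area, numeric(1))
  truth <- truth / sum(truth)
  rec <- t(vapply(1:25, function(r) {
    sp <- gen_spectrum(comps, c(-203.5, -197.5), 1024,
                       noise = noise_spec(0.01, seed = r, kind = "relative"))
    d <- deconvolve_1d(sp, c(-199.7, -200.9, -201.0))
    o <- order(d$components$center_ppm, decreasing = TRUE)
    d$components$population[o]
  }, numeric(3)))
  for (k in 1:3) {
    sdk <- sd(rec[, k])
    expect_lt(abs(mean(rec[, k]) - truth[k]), 3 * sdk / sqrt(nrow(rec)) + 1e-3)
  }
})

test_that("near-coincident components are flagged as merged", {
  comps <- list(lorentzian_component(1.0, -200.00, 40),
                lorentzian_component(0.8, -200.005, 40))
  sp <- gen_spectrum(comps, c(-202, -198), 512)
  expect_warning(deconvolve_1d(sp, c(-200.0, -200.01)), "1/4 FWHM")
})

test_that("eta is linear in S2_tc with the expected prefactor", {
  expect_equal(eta_from_s2tc(0), 0)
  # frozen: direct CODATA substitution gives 3.60900 s^-1 per ns
  expect_equal(eta_from_s2tc(1), 3.60900, tolerance = 1e-5)
  expect_equal(eta_from_s2tc(37), 133.533, tolerance = 1e-5)
  # r^-6 law: doubling the proton distance divides eta by 64
  c2 <- physical_constants(r_HH = 2 * 1.813e-10)
  expect_equal(eta_from_s2tc(10, c2), eta_from_s2tc(10) / 64,
               tolerance = 1e-12)
  # exact inverse
  s2 <- seq(0.5, 60, length.out = 20)
  expect_equal(s2tc_from_eta(eta_from_s2tc(s2)), s2, tolerance = 1e-12)
})

test_that("ratio curve obeys its algebraic limits", {
  expect_equal(ratio_curve(100, 20, 0), 0)
  # delta = 0 reduction
  Td <- seq(0, 0.03, length.out = 7)
  expect_equal(ratio_curve(80, 0, Td), 0.75 * tanh(80 * Td), tolerance = 1e-12)
  expect_true(all(ratio_curve(80, 0, Td) <= 0.75))
  expect_true(all(diff(ratio_curve(80, 5, Td)) >= 0))
  # frozen from a symbolic evaluation of the full expression
  expect_equal(ratio_curve(100, 20, 0.01), 0.66679249, tolerance = 1e-7)
  # long-delay plateau 0.75 eta / (sqrt(eta^2+delta^2) - delta)
  lam <- sqrt(100^2 + 20^2)
  expect_equal(ratio_curve(100, 20, 10), 0.75 * 100 / (lam - 20),
               tolerance = 1e-9)
})

test_that("relaxation fit recovers S2_tc and rejects unphysical data", {
  rr <- gen_relaxation(10, 3)
  f <- fit_relaxation(rr, mc_replicates = 0)
  expect_equal(f$estimates[["S2_tc"]], 10, tolerance = 1e-4)
  expect_equal(f$estimates[["delta"]], 3, tolerance = 1e-3)
  # absolute-scale sensitivity: a 10% intensity miscalibration shifts the fit
  rr2 <- rr; rr2$ratio <- 1.1 * rr2$ratio
  f2 <- fit_relaxation(rr2, mc_replicates = 0)
  expect_gt(abs(f2$estimates[["S2_tc"]] - f$estimates[["S2_tc"]]),
            0.02 * f$estimates[["S2_tc"]])
  bad <- data.frame(delay_s = c(0.01, 0.02, 0.03, 0.04),
                    ratio = c(0.1, 0.3, 0.76, 0.5))
  expect_error(fit_relaxation(bad, mc_replicates = 0), "ceiling")
})

test_that("two-point R2 follows the log ratio", {
  expect_equal(r2_two_point(1, 1, 0.015), 0)
  expect_equal(r2_two_point(0.5, 1, 0.015), log(2) / 0.015, tolerance = 1e-12)
  expect_equal(r2_two_point(exp(-1), 1, 0.015), 1 / 0.015, tolerance = 1e-12)
  expect_warning(r2_two_point(1.1, 1, 0.015), "negative")
})
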