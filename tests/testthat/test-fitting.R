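test_that("van't Hoff fit recovers noise-free parameters exactly", {
  m <- gen_melt(-73, -220, 1e-4)
  f <- fit_melt(m, 1e-4, mc_replicates = 0)
  expect_equal(f$estimates[["dH"]], -73, tolerance = 1e-6)
  expect_equal(f$estimates[["dS"]], -220, tolerance = 1e-6)
  expect_lt(f$sigma, 1e-8)
})

test_that("van't Hoff fit recovers noisy parameters within 3 MC sd", {
  m <- gen_melt(-73, -220, 1e-4, noise = noise_spec(0.02, seed = 7))
  f <- fit_melt(m, 1e-4, mc_replicates = 300, seed = 11)
  expect_lt(abs(f$estimates[["dH"]] + 73), 3 * f$mc_sd[["dH"]])
  expect_lt(abs(f$estimates[["dS"]] + 220), 3 * f$mc_sd[["dS"]])
})

test_that("melt fit refuses data without a transition", {
  flat <- data.frame(temperature_C = c(20, 25, 30, 35),
                     F_ss = rep(1e-4, 4), F_ds = 1 - rep(1e-4, 4))
  expect_error(fit_melt(flat, 1e-4, mc_replicates = 0), "transition")
  expect_error(fit_melt(flat[1:3, ], 1e-4, mc_replicates = 0), "4 temperatures")
})

test_that("one-site global fit recovers Kd and is scale invariant", {
  reps <- c("M221", "M355", "M370", "M380")
  tt <- gen_titration(0, 17e-6, seq(0, 2e-4, length.out = 8), 5e-5,
                      reporters = reps)
  f <- fit_titration_one_site(tt, mc_replicates = 0)
  expect_equal(f$estimates[["Kd"]], 17e-6, tolerance = 1e-5)
  # doubling one reporter's intensities changes its scales, not Kd
  tt2 <- tt
  sel <- tt2$reporter == "M221"
  tt2$intensity[sel] <- 2 * tt2$intensity[sel]
  f2 <- fit_titration_one_site(tt2, mc_replicates = 0)
  expect_equal(f2$estimates[["Kd"]], f$estimates[["Kd"]], tolerance = 1e-6)
  expect_equal(unname(f2$nuisance$scales["M221.free"]),
               unname(2 * f$nuisance$scales["M221.free"]), tolerance = 1e-6)
})

test_that("one-site fit flags an uninformative series", {
  # ligand always in vast excess: every point fully bound
  tt <- gen_titration(0, 1e-9, rep(1e-2, 4), 5e-5, reporters = "M221")
  expect_error(fit_titration_one_site(tt, mc_replicates = 0),
               "no binding information")
})

test_that("noisy one-site fit recovers within 3 MC sd", {
  reps <- c("M221", "M355", "M370", "M380")
  tt <- gen_titration(0, 17e-6, seq(0, 2e-4, length.out = 8), 5e-5,
                      reporters = reps,
                      noise = noise_spec(0.05, seed = 5, kind = "relative"))
  f <- fit_titration_one_site(tt, mc_replicates = 300, seed = 9)
  expect_lt(abs(f$estimates[["Kd"]] - 17e-6), 3 * f$mc_sd[["Kd"]])
})

test_that("coupled fit recovers noise-free constants", {
  pop <- gen_titration(36000, 15e-6, 1e-4, seq(0, 3e-4, length.out = 8))
  f <- fit_coupled(pop, 1e-4, mc_replicates = 0)
  expect_equal(f$estimates[["Km"]], 36000, tolerance = 1e-4)
  expect_equal(f$estimates[["Kd"]], 15e-6, tolerance = 1e-4)
})

test_that("coupled fit with Km fixed at zero nests the one-site model", {
  pop <- gen_titration(0, 17e-6, 1e-4, seq(1e-5, 3e-4, length.out = 8))
  f <- fit_coupled(pop, 1e-4, Km_fixed = 0, mc_replicates = 0)
  expect_equal(f$estimates[["Kd"]], 17e-6, tolerance = 1e-5)
})

test_that("Monte-Carlo errors vanish with noise and scale with it", {
  m <- gen_melt(-73, -220, 1e-4)
  f0 <- fit_melt(m, 1e-4, mc_replicates = 25, seed = 3)
  expect_lt(f0$mc_sd[["dH"]], 1e-6 * abs(f0$estimates[["dH"]]))
  sds <- vapply(c(0.01, 0.05), function(lvl) {
    mm <- gen_melt(-73, -220, 1e-4, noise = noise_spec(lvl, seed = 13))
    fit_melt(mm, 1e-4, mc_replicates = 150, seed = 17)$mc_sd[["dH"]]
  }, numeric(1))
  # roughly linear growth over a 5x noise range
  expect_gt(sds[2] / sds[1], 2.5)
  expect_lt(sds[2] / sds[1], 10)
})

test_that("identical seed and data give bit-identical fits", {
  m <- gen_melt(-73, -220, 1e-4, noise = noise_spec(0.02, seed = 21))
  a <- fit_melt(m, 1e-4, mc_replicates = 50, seed = 23)
  b <- fit_melt(m, 1e-4, mc_replicates = 50, seed = 23)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$mc_sd, b$mc_sd)
  expect_identical(a$mc_ensemble, b$mc_ensemble)
})
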