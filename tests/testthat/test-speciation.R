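test_that("hybridization-only speciation matches the closed form", {
  # no-duplex limit
  st <- solve_hybridization(1e-4, 0)
  expect_equal(st$ssRNA_free, 1e-4)
  expect_equal(st$dsRNA, 0)
  # melting-midpoint condition Km = 1/L_T gives F_ss = 1/2
  expect_equal(populations(solve_hybridization(1e-4, 1e4))$F_ssRNA, 0.5,
               tolerance = 1e-12)
  # stable duplex: tiny single-strand fraction survives the cancellation
  expect_equal(populations(solve_hybridization(1e-4, 4e12))$F_ssRNA,
               3.5355e-5, tolerance = 1e-4)
  # against the naive quadratic at moderate Km
  for (Km in c(1, 1e3, 1e6)) {
    expect_equal(solve_hybridization(1e-4, Km)$ssRNA_free,
                 oracle_hybridization_ss(1e-4, Km), tolerance = 1e-10)
  }
  expect_error(solve_hybridization(-1, 1), "non-negative")
})

test_that("one-site speciation solves the exact quadratic", {
  st <- solve_one_site(50e-6, 100e-6, 17e-6)
  # frozen from an independent bisection on the mass balance
  expect_equal(st$complex / st$C_T, 0.78180, tolerance = 1e-4)
  expect_gte(st$complex / st$C_T, 0.70)
  expect_equal(solve_one_site(5e-5, 0, 1e-6)$complex, 0)
  # isotherm limit: C_T >> L_T and C_T = Kd binds half the ligand
  st2 <- solve_one_site(1e-3, 1e-9, 1e-3)
  expect_equal(st2$complex / st2$L_T, 0.5, tolerance = 1e-3)
  expect_error(solve_one_site(1, 1, 0), "positive")
})

test_that("coupled solver agrees with brute-force bisection", {
  set.seed(101)
  n <- 250
  C_T <- 10^runif(n, -9, -2)
  L_T <- 10^runif(n, -9, -2)
  Km <- 10^runif(n, 0, 14)
  Kd <- 10^runif(n, -9, -3)
  for (i in seq_len(n)) {
    got <- solve_coupled(C_T[i], L_T[i], Km[i], Kd[i])$ssRNA_free
    want <- oracle_coupled_ss(C_T[i], L_T[i], Km[i], Kd[i])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("both mass balances hold to 1e-9 relative on random inputs", {
  set.seed(202)
  for (i in 1:200) {
    C_T <- 10^runif(1, -9, -2); L_T <- 10^runif(1, -9, -2)
    Km <- 10^runif(1, 0, 14); Kd <- 10^runif(1, -9, -3)
    st <- solve_coupled(C_T, L_T, Km, Kd)
    expect_true(all(c(st$ssRNA_free, st$dsRNA, st$protein_free,
                      st$complex) >= 0))
    expect_equal(st$ssRNA_free + 2 * st$dsRNA + st$complex, L_T,
                 tolerance = 1e-9)
    expect_equal(st$protein_free + st$complex, C_T, tolerance = 1e-9)
    # equilibrium definitions are satisfied
    expect_equal(st$dsRNA, Km * st$ssRNA_free^2, tolerance = 1e-9)
    expect_equal(st$protein_free * st$ssRNA_free / st$complex, Kd,
                 tolerance = 1e-6)
  }
})

test_that("coupled model reduces to hybridization without protein", {
  a <- solve_coupled(0, 1e-4, 4e12, 17e-6)
  b <- solve_hybridization(1e-4, 4e12)
  expect_equal(a$ssRNA_free, b$ssRNA_free, tolerance = 1e-12)
  expect_equal(a$complex, 0)
})

test_that("trace-ligand limit recovers the apparent unwinding constant", {
  Km <- 1e6; Kd <- 1e-5
  st <- solve_coupled(1e-4, 1e-12, Km, Kd)
  lhs <- st$protein_free^2 * st$dsRNA / st$complex^2
  expect_equal(lhs, kd_apparent(Km, Kd), tolerance = 1e-3)
})

test_that("populations are normalized fractions", {
  st <- solve_coupled(3e-4, 1e-4, 4e12, 1.7e-5)
  p <- populations(st)
  expect_equal(p$F_ssRNA + p$F_dsRNA + p$F_bound, 1, tolerance = 1e-9)
  expect_true(all(unlist(p) >= 0 & unlist(p) <= 1))
  expect_error(populations(solve_coupled(1e-4, 0, 1e3, 1e-6)), "L_T = 0")
})

test_that("bound fraction grows with protein; duplex with RNA", {
  f_bound <- vapply(c(1, 3, 10, 30, 100) * 1e-6, function(ct)
    populations(solve_coupled(ct, 1e-4, 1e4, 1e-5))$F_bound, numeric(1))
  expect_true(all(diff(f_bound) > 0))
  f_ds <- vapply(c(1, 3, 10, 30, 100) * 1e-6, function(lt)
    populations(solve_coupled(1e-5, lt, 1e5, 1e-5))$F_dsRNA, numeric(1))
  expect_true(all(diff(f_ds) > 0))
})

test_that("melt curve rises monotonically and crosses at the predicted Tm", {
  mc <- melt_curve(thermo_params(-73, -220), 1e-4,
                   seq(280, 340, length.out = 121))
  expect_true(all(diff(mc$F_ss) > 0))
  # closed-form midpoint: dH - T dS = -R T ln(1/L_T) => T = 306.335 K
  Tm <- approx(mc$F_ss, mc$T_K, xout = 0.5)$y
  expect_equal(Tm, 306.335, tolerance = 1e-3)
  expect_error(melt_curve(thermo_params(-73, -220), 1e-4, 400),
               "273-373")
})
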