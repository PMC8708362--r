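test_that("Langevin function matches its limits, series and direct values", {
  expect_identical(langevin(0), 0)
  expect_gte(langevin(1e3), 0.999)
  expect_equal(langevin(8.034), 0.8755292, tolerance = 1e-6)
  # odd, strictly increasing, bounded by min(1, xi/3)
  xi <- c(1e-6, 1e-4, 1e-2, 0.5, 1, 5, 20, 100)
  expect_equal(langevin(-xi), -langevin(xi))
  expect_true(all(diff(langevin(xi)) > 0))
  expect_true(all(langevin(xi) < pmin(1, xi / 3)))
  # series and direct branches agree through the switch point
  # the direct form loses ~8 digits to cancellation at xi ~ 1e-4, so the
  # two branches can only be expected to agree to ~1e-6 relative
  near <- seq(0.5e-4, 2e-4, length.out = 41)
  expect_equal(langevin(near), 1 / tanh(near) - 1 / near, tolerance = 1e-6)
  expect_error(langevin(NaN), class = "ferroheat_domain_error")
})

test_that("ensemble magnetization follows Msat * L(xi)", {
  expect_identical(langevin_magnetization(480e3, 0), 0)
  expect_equal(langevin_magnetization(480e3, 1e4), 480e3, tolerance = 1e-3)
  expect_equal(langevin_magnetization(480e3, 8.034), 480e3 * 0.8755292,
               tolerance = 1e-6)
  expect_error(langevin_magnetization(-1, 1), class = "ferroheat_domain_error")
})

test_that("Neel relaxation time is the Arrhenius law over the pi K D^3/6 barrier", {
  expect_equal(neel_relaxation_time(0, 10e-9), 1e-9)
  expect_equal(neel_relaxation_time(11e3, 17.4e-9), 1.518462e-6, tolerance = 1e-6)
  expect_equal(neel_relaxation_time(200e3, 6.7e-9), 2.006429e-6, tolerance = 1e-6)
  # monotone in K and D
  expect_true(all(diff(neel_relaxation_time(seq(10e3, 300e3, 10e3), 10e-9)) > 0))
  expect_true(all(diff(neel_relaxation_time(100e3, seq(5, 15, 1) * 1e-9)) > 0))
  expect_error(neel_relaxation_time(5e6, 50e-9), "overflow",
               class = "ferroheat_overflow_error")
})

test_that("Langevin argument and initial susceptibility scale as the closed forms", {
  expect_identical(xi_argument(480e3, 17.4e-9, 0), 0)
  expect_equal(xi_argument(480e3, 17.4e-9, 20e3), 8.033835, tolerance = 1e-6)
  expect_equal(xi_argument(480e3, 17.4e-9, 40e3) /
               xi_argument(480e3, 17.4e-9, 20e3), 2)
  expect_identical(initial_susceptibility(480e3, 17.4e-9, epsilon = 0), 0)
  expect_equal(initial_susceptibility(480e3, 17.4e-9), 6.427068, tolerance = 1e-6)
  expect_equal(initial_susceptibility(480e3, 2 * 17.4e-9) /
               initial_susceptibility(480e3, 17.4e-9), 8, tolerance = 1e-12)
})

test_that("static susceptibility interpolates from chi_i to the saturated tail", {
  expect_equal(static_susceptibility(1, 1e-9), 1)
  expect_equal(static_susceptibility(6.427068, 8.033835), 2.101264,
               tolerance = 1e-6)
  # chi0/chi_i nonincreasing in xi and always within (0, 1]
  xi <- seq(0, 50, by = 0.05)
  ratio <- static_susceptibility(1, xi)
  expect_true(all(diff(ratio) <= 0))
  expect_true(all(ratio > 0 & ratio <= 1))
})

test_that("Debye components satisfy the half-chi0 bound and extreme-u asymptotes", {
  at1 <- debye_components(2, f = 1 / (2 * pi), tau = 1)  # omega tau = 1
  expect_equal(at1$chi_imag, 1)
  expect_equal(at1$chi_real, 1)
  at0 <- debye_components(2, f = 0, tau = 1)
  expect_equal(c(at0$chi_real, at0$chi_imag), c(2, 0))
  big <- debye_components(1, f = 1e6 / (2 * pi), tau = 1)  # u = 1e6
  expect_equal(big$chi_imag, 1e-6, tolerance = 1e-6)
  expect_true(is.finite(big$chi_imag))
  u <- 10^seq(-8, 8, by = 0.25)
  deb <- debye_components(1, f = u / (2 * pi), tau = 1)
  expect_true(all(deb$chi_imag <= 0.5 + 1e-15))
  expect_equal(deb$chi_real, 1 / (1 + u^2), tolerance = 1e-12)
})

test_that("specific loss power reproduces direct scalar evaluation of the model", {
  # zero field dissipates nothing
  expect_equal(specific_loss_power(0, 16e-9, H = 0, f = 500e3)$Ps, 0)
  # magnetite at its sharpest operating points (independent scalar oracle)
  r1 <- specific_loss_power(0, 16.1e-9, H = 10e3, f = 500e3)
  expect_equal(r1$Ps, oracle_ps(11e3, 480e3, 5240, 16.1e-9, 10e3, 500e3),
               tolerance = 1e-12)
  expect_equal(r1$Ps, 62.29, tolerance = 2e-3)
  r2 <- specific_loss_power(0, 17.4e-9, H = 20e3, f = 100e3)
  expect_equal(r2$Ps, 31.69, tolerance = 0.01)
  # intermediate record is self-consistent
  expect_equal(r1$chi_real, r1$chi0 / (1 + r1$omega_tau^2))
  expect_equal(r1$chi_imag, r1$chi0 * r1$omega_tau / (1 + r1$omega_tau^2))
  expect_equal(r1$langevin, langevin(r1$xi))
})

test_that("dissipation route via Debye chi'' equals the composite closed form", {
  set.seed(421)
  n <- 1e4
  x <- sample(anchor_x, n, replace = TRUE)
  D <- runif(n, 1e-9, 20e-9)
  H <- runif(n, 10e3, 50e3)
  f <- runif(n, 100e3, 500e3)
  got <- specific_loss_power(x, D, H, f)$Ps
  props <- material_properties(x)
  want <- oracle_ps(props$K, props$Ms, props$rho, D, H, f)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(is.finite(got)) && all(got >= 0))
})

test_that("loss power increases with field amplitude and frequency", {
  H <- seq(10e3, 50e3, by = 5e3)
  ps_H <- specific_loss_power(0, 16e-9, H, 250e3)$Ps
  expect_true(all(diff(ps_H) > 0))
  f <- seq(100e3, 500e3, by = 50e3)
  ps_f <- specific_loss_power(0.4, 6e-9, 20e3, f)$Ps
  expect_true(all(diff(ps_f) > 0))
})

test_that("linear-response limit: Ps/H^2 converges as H -> 0", {
  D <- 12e-9; f <- 250e3; x <- 0.1
  p <- material_properties(x)
  tau <- neel_relaxation_time(p$K, D)
  u <- 2 * pi * f * tau
  chi_i <- initial_susceptibility(p$Ms, D)
  lim <- pi * mu0_ * chi_i * u / (1 + u^2) * f / p$rho / 1000  # W/g per (A/m)^2
  H <- 1e-2  # xi ~ 1e-6 << 1e-3
  got <- specific_loss_power(x, D, H, f)$Ps / H^2
  expect_equal(got, lim, tolerance = 1e-4)
})

test_that("loss power is finite with one interior diameter peak across the study box", {
  D <- seq(1e-9, 20e-9, by = 1e-11)
  for (xv in anchor_x) {
    ps <- specific_loss_power(xv, D, 20e3, 500e3)$Ps
    expect_true(all(is.finite(ps)))
    i <- which.max(ps)
    expect_gt(i, 1L); expect_lt(i, length(D))
    # single peak: rises before, falls after (up to floating rounding)
    eps <- 1e-12 * ps[i]
    expect_true(all(diff(ps[1:i]) >= -eps))
    expect_true(all(diff(ps[i:length(ps)]) <= eps))
  }
})
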