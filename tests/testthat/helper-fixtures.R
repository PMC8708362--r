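# Shared fixtures and an independent scalar oracle for the loss-power model.
#
# The oracle evaluates the one-line closed form directly (no package
# intermediates), so route-equivalence tests compare two genuinely
# different code paths.

kB_ <- 1.380649e-23
mu0_ <- 4 * pi * 1e-7

# anchor compositions with full property coverage (x = 1.1 has K only)
anchor_x <- c(0, 0.05, 0.1, 0.2, 0.4, 0.67, 0.8, 1)

# direct one-line evaluation of the composite loss-power formula
# Ps = 3 pi mu0 (chi_i / rho xi) L(xi) [2 pi f tau / (1 + (2 pi f tau)^2)] f H^2
# in W/g, given explicit material constants
oracle_ps <- function(K, Ms, rho, D, H, f, epsilon = 0.1, tau0 = 1e-9, T = 300) {
  xi <- pi * mu0_ * Ms * D^3 * H / (6 * kB_ * T)
  L <- 1 / tanh(xi) - 1 / xi
  chi_i <- epsilon * pi * mu0_ * Ms^2 * D^3 / (18 * kB_ * T)
  tau <- tau0 * exp(pi * K * D^3 / (6 * kB_ * T))
  u <- 2 * pi * f * tau
  3 * pi * mu0_ * chi_i / (rho * xi) * L * u / (1 + u^2) * f * H^2 / 1000
}

# brute-force argmax of the oracle on a uniform diameter grid
oracle_argmax <- function(K, Ms, rho, H, f, step = 1e-12,
                          D_range = c(1e-9, 20e-9), ...) {
  D <- seq(D_range[1], D_range[2], by = step)
  ps <- oracle_ps(K, Ms, rho, D, H, f, ...)
  i <- which.max(ps)
  list(D = D[i], Ps = ps[i])
}

anchor_props <- function(x) {
  a <- cofe_anchors()
  i <- match(x, a$x)
  list(K = a$K[i], Ms = a$Ms[i], rho = a$rho[i])
}
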