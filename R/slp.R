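# Physics kernel: Langevin statics, Neel relaxation, Debye susceptibility
# and the specific loss power of a monodisperse superparamagnetic ensemble.
#
# All computation is strict SI.  The loss power is reported in W/g
# (= SI W/kg / 1000), the convention in which hyperthermia dose tables are
# printed; the SI value is always Ps * 1000.

#' Langevin function
#'
#' `L(xi) = coth(xi) - 1/xi`, the equilibrium magnetization law of
#' non-interacting superparamagnetic moments.  A series branch
#' `xi/3 - xi^3/45` is used for `|xi| <= 1e-4`, where the direct form loses
#' all significance to cancellation.
#'
#' @param xi Dimensionless field argument; any finite value (odd function).
#' @return `L(xi)`, in (-1, 1), vectorized.
#' @examples
#' langevin(c(0, 1, 10))
#' @export
langevin <- function(xi) {
  check_finite(xi, "xi")
  small <- abs(xi) <= 1e-4
  out <- numeric(length(xi))
  out[small] <- xi[small] / 3 - xi[small]^3 / 45
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

# L(xi)/xi with the analytic limit 1/3 at xi = 0; used by the static
# susceptibility so chi0 -> chi_i smoothly.
langevin_over_xi <- function(xi) {
  check_finite(xi, "xi")
  small <- abs(xi) <= 1e-4
  out <- numeric(length(xi))
  out[small] <- 1 / 3 - xi[small]^2 / 45
  xl <- xi[!small]
  out[!small] <- (1 / tanh(xl) - 1 / xl) / xl
  out
}

#' Ensemble magnetization from the Langevin law
#'
#' `M = Msat * L(xi)`: the equilibrium magnetization of the ensemble at
#' saturation magnetization `Msat` and Langevin argument `xi`.
#'
#' @param Msat Saturation magnetization, A/m (non-negative).
#' @param xi Dimensionless Langevin argument.
#' @return Magnetization in A/m.
#' @export
langevin_magnetization <- function(Msat, xi) {
  check_range(Msat, "Msat", 0)
  Msat * langevin(xi)
}

#' Neel relaxation time
#'
#' `tau = tau0 * exp(pi * K * D^3 / (6 kB T))`: thermally activated
#' reorientation of the particle moment over the anisotropy barrier
#' `pi K D^3 / 6` (sphere volume times K).
#'
#' @param K Anisotropy constant, J/m3 (non-negative).
#' @param D Particle diameter, m (positive).
#' @param tau0 Attempt time, s; default `1e-9`.
#' @param T Absolute temperature, K; default 300.
#' @return Relaxation time in s, vectorized.
#' @examples
#' neel_relaxation_time(11e3, 17.4e-9)
#' @export
neel_relaxation_time <- function(K, D, tau0 = 1e-9, T = 300) {
  check_range(K, "K", 0)
  check_range(D, "D", 0, lower_open = TRUE)
  check_range(tau0, "tau0", 0, lower_open = TRUE)
  check_range(T, "T", 0, lower_open = TRUE)
  expo <- pi * K * D^3 / (6 * .kB * T)
  if (any(expo > 700)) {
    abort(sprintf(
      "Neel exponent pi*K*D^3/(6 kB T) = %.1f would overflow exp(); reduce K or D.",
      max(expo)), class = "ferroheat_overflow_error")
  }
  tau0 * exp(expo)
}

#' Langevin argument of the applied field
#'
#' `xi = pi * mu0 * Ms * D^3 * H / (6 kB T)`: Zeeman energy of one particle
#' moment in the field over thermal energy.  Linear in `H`, cubic in `D`.
#'
#' @param Ms Spontaneous magnetization, A/m.
#' @param D Particle diameter, m.
#' @param H Field amplitude, A/m.
#' @param T Absolute temperature, K.
#' @return Dimensionless `xi`, vectorized.
#' @export
xi_argument <- function(Ms, D, H, T = 300) {
  check_range(Ms, "Ms", 0)
  check_range(D, "D", 0, lower_open = TRUE)
  check_range(H, "H", 0)
  check_range(T, "T", 0, lower_open = TRUE)
  pi * .mu0 * Ms * D^3 * H / (6 * .kB * T)
}

#' Initial magnetic susceptibility of the ensemble
#'
#' `chi_i = epsilon * pi * mu0 * Ms^2 * D^3 / (18 kB T)`.  The packing
#' volumetric fraction `epsilon` (magnetic volume over total volume of the
#' dispersion) scales the response of the dilute ensemble.
#'
#' @inheritParams xi_argument
#' @param epsilon Packing volumetric fraction in (0, 1\]; default 0.1.
#' @return Dimensionless initial susceptibility, vectorized.
#' @export
initial_susceptibility <- function(Ms, D, epsilon = 0.1, T = 300) {
  check_range(Ms, "Ms", 0)
  check_range(D, "D", 0, lower_open = TRUE)
  check_range(epsilon, "epsilon", 0, 1)
  check_range(T, "T", 0, lower_open = TRUE)
  epsilon * pi * .mu0 * Ms^2 * D^3 / (18 * .kB * T)
}

#' Static susceptibility from the Langevin law
#'
#' `chi0 = 3 chi_i * L(xi) / xi`, with the analytic limit `chi0 -> chi_i`
#' as `xi -> 0`.  Always in (0, chi_i\].
#'
#' @param chi_i Initial susceptibility (dimensionless, non-negative).
#' @param xi Langevin argument (non-negative).
#' @return Static susceptibility, vectorized.
#' @export
static_susceptibility <- function(chi_i, xi) {
  check_range(chi_i, "chi_i", 0)
  check_range(xi, "xi", 0)
  3 * chi_i * langevin_over_xi(xi)
}

#' Debye in-phase and out-of-phase susceptibility
#'
#' First-order relaxational response at angular frequency `omega = 2 pi f`:
#' `chi' = chi0 / (1 + (omega tau)^2)` and
#' `chi'' = chi0 * omega tau / (1 + (omega tau)^2)`.  The out-of-phase
#' factor is evaluated as `1 / (u + 1/u)` (u = omega tau), which cannot
#' overflow for extreme `u` and makes the `chi'' <= chi0/2` bound explicit.
#'
#' @param chi0 Static susceptibility (non-negative).
#' @param f Field frequency, Hz (non-negative).
#' @param tau Relaxation time, s (positive).
#' @return A tibble with columns `chi_real` and `chi_imag`.
#' @examples
#' debye_components(1, f = 1 / (2 * pi), tau = 1)  # omega tau = 1
#' @export
debye_components <- function(chi0, f, tau) {
  check_range(chi0, "chi0", 0)
  check_range(f, "f", 0)
  check_range(tau, "tau", 0, lower_open = TRUE)
  u <- 2 * pi * f * tau
  fac <- ifelse(u > 0, 1 / (u + 1 / u), 0)
  tibble(chi_real = chi0 / (1 + u^2), chi_imag = chi0 * fac)
}

#' Specific loss power of Co-ferrite nanoparticles
#'
#' Full evaluation of the Neel-relaxation loss-power model at composition
#' `x`: material properties from the anchor models, Langevin argument,
#' initial and static susceptibilities, Neel relaxation time, Debye
#' components and finally
#' `Ps = pi * mu0 * chi'' * f * H^2 / rho`.
#'
#' `Ps` is reported in W per gram of magnetic material (the customary scale
#' of hyperthermia dose tables); multiply by 1000 for the SI value in W/kg.
#' All intermediate quantities are exposed in the result.
#'
#' @param x Co2+ concentration(s) in \[0, 1\].
#' @param D Particle diameter, m.
#' @param H Field amplitude, A/m.
#' @param f Field frequency, Hz.
#' @param epsilon Packing volumetric fraction; default 0.1.
#' @param tau0 Attempt time, s; default 1e-9.
#' @param T Temperature, K; default 300.
#' @param anchors Material anchor table, see [cofe_anchors()].
#' @return A tibble (class `slp_tbl`), one row per evaluation point, with
#'   columns `x`, `D`, `H`, `f`, `xi`, `langevin`, `chi_i`, `chi0`, `tau`,
#'   `omega_tau`, `chi_real`, `chi_imag` and `Ps` (W/g).
#' @examples
#' specific_loss_power(x = 0, D = 16.1e-9, H = 10e3, f = 500e3)
#' @export
specific_loss_power <- function(x, D, H, f, epsilon = 0.1, tau0 = 1e-9,
                                T = 300, anchors = cofe_anchors()) {
  props <- material_properties(x, anchors)
  xi <- xi_argument(props$Ms, D, H, T)
  Lx <- langevin(xi)
  chi_i <- initial_susceptibility(props$Ms, D, epsilon, T)
  chi0 <- static_susceptibility(chi_i, xi)
  tau <- neel_relaxation_time(props$K, D, tau0, T)
  check_range(f, "f", 0)
  deb <- debye_components(chi0, f, tau)
  ps_si <- pi * .mu0 * deb$chi_imag * f * H^2 / props$rho
  out <- tibble(
    x = props$x, D = D, H = H, f = f,
    xi = xi, langevin = Lx, chi_i = chi_i, chi0 = chi0,
    tau = tau, omega_tau = 2 * pi * f * tau,
    chi_real = deb$chi_real, chi_imag = deb$chi_imag,
    Ps = ps_si / 1000
  )
  class(out) <- c("slp_tbl", class(out))
  out
}
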