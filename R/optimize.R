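# Optimal-diameter search: the loss power at fixed (x, H, f) is sharply
# peaked in D (Neel time sweeps through the 1/omega resonance as D^3 moves
# the barrier), so the peak is located by a coarse scan of the whole search
# interval followed by golden-section refinement between the bracketing
# neighbours.

#' Diameter maximizing the specific loss power
#'
#' Finds the particle diameter `D_M` that maximizes `Ps` at a given
#' composition, field amplitude and frequency.  A coarse scan at
#' `coarse_step` resolution locates the global peak (no unimodality
#' assumption), then [stats::optimize()] refines it between the bracketing
#' grid neighbours to sub-picometre precision.
#'
#' @inheritParams specific_loss_power
#' @param x Single Co2+ concentration in \[0, 1\].
#' @param H Field amplitude, A/m (positive; a zero field has no maximum).
#' @param f Field frequency, Hz (positive).
#' @param D_range Search interval in m; default 1--20 nm.
#' @param coarse_step Coarse-scan step in m; default 0.05 nm.
#' @param tol Refinement tolerance on D, m; default 1e-13 (1e-4 nm).
#' @return An object of class `slp_optimum`: a list with `D_M` (m), `PsM`
#'   (W/g), the inputs `x`, `H`, `f`, a `boundary` flag (optimum at the
#'   search-interval edge), and `detail`, the full [specific_loss_power()]
#'   record at the optimum.  Use [tidy()] or [glance()] for tibble views.
#' @examples
#' opt <- find_optimal_diameter(x = 0, H = 20e3, f = 500e3)
#' tidy(opt)
#' @export
find_optimal_diameter <- function(x, H, f, D_range = c(1e-9, 20e-9),
                                  epsilon = 0.1, tau0 = 1e-9, T = 300,
                                  coarse_step = 5e-11, tol = 1e-13,
                                  anchors = cofe_anchors()) {
  stopifnot(length(x) == 1L, length(H) == 1L, length(f) == 1L,
            length(D_range) == 2L, D_range[1] > 0, D_range[2] > D_range[1])
  if (H <= 0 || f <= 0) {
    abort("no interior maximum: Ps is identically zero when H = 0 or f = 0.",
          class = "ferroheat_flat_objective_error")
  }
  ps_at <- function(D) {
    specific_loss_power(x, D, H, f, epsilon, tau0, T, anchors)$Ps
  }
  D_grid <- seq(D_range[1], D_range[2], by = coarse_step)
  if (D_grid[length(D_grid)] < D_range[2]) D_grid <- c(D_grid, D_range[2])
  ps <- ps_at(D_grid)
  i <- which.max(ps)
  # near-degenerate second peak: keep the smaller diameter, warn
  others <- which(ps >= ps[i] * (1 - 1e-9))
  if (any(abs(others - i) > 1L)) {
    i <- min(others)
    warn("multiple near-equal loss-power maxima; reporting the smallest diameter.")
  }
  lo <- D_grid[max(1L, i - 1L)]
  hi <- D_grid[min(length(D_grid), i + 1L)]
  ref <- optimize(ps_at, lower = lo, upper = hi, maximum = TRUE, tol = tol)
  D_M <- ref$maximum
  detail <- specific_loss_power(x, D_M, H, f, epsilon, tau0, T, anchors)
  boundary <- i == 1L || i == length(D_grid)
  if (boundary) {
    # true edge optimum: report the edge, not the golden-section interior point
    edge <- D_grid[i]
    if (ps[i] >= detail$Ps) {
      D_M <- edge
      detail <- specific_loss_power(x, edge, H, f, epsilon, tau0, T, anchors)
    }
    warn(sprintf("loss-power maximum lies at the search boundary (D = %.3g m).", D_M))
  }
  structure(
    list(D_M = D_M, PsM = detail$Ps, x = x, H = H, f = f,
         boundary = boundary, detail = detail,
         params = list(epsilon = epsilon, tau0 = tau0, T = T,
                       D_range = D_range, coarse_step = coarse_step, tol = tol)),
    class = "slp_optimum"
  )
}

#' @export
print.slp_optimum <- function(x, ...) {
  cat(sprintf(
    "<slp_optimum>  x = %g, H = %g kA/m, f = %g kHz\n  D_M = %.2f nm   PsM = %.2f W/g%s\n",
    x$x, x$H / 1e3, x$f / 1e3, x$D_M * 1e9, x$PsM,
    if (x$boundary) "   [boundary optimum]" else ""))
  invisible(x)
}

#' @rdname find_optimal_diameter
#' @param x An `slp_optimum` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy slp_optimum
#' @export
tidy.slp_optimum <- function(x, ...) {
  obj <- x
  tibble(x = obj$x, H = obj$H, f = obj$f, D_M = obj$D_M, PsM = obj$PsM,
         boundary = obj$boundary)
}

#' @rdname find_optimal_diameter
#' @method glance slp_optimum
#' @export
glance.slp_optimum <- function(x, ...) {
  tibble(D_M_nm = x$D_M * 1e9, PsM_W_per_g = x$PsM,
         xi = x$detail$xi, omega_tau = x$detail$omega_tau,
         chi_imag = x$detail$chi_imag, boundary = x$boundary)
}

#' Loss-power surface over diameter and frequency
#'
#' Evaluates `Ps` on the full (D, f) grid at fixed composition and field
#' amplitude -- the surface whose ridge line traces the optimal diameter.
#'
#' @inheritParams find_optimal_diameter
#' @param D,f Strictly increasing grid vectors (m, Hz).
#' @return A tibble (class `slp_surface`) in long format with one row per
#'   (D, f) cell and columns `x`, `D`, `f`, `H`, `Ps`.
#' @examples
#' ps_surface(x = 0, D = seq(14, 19, 0.5) * 1e-9, f = c(100e3, 500e3), H = 20e3)
#' @export
ps_surface <- function(x, D, f, H, epsilon = 0.1, tau0 = 1e-9, T = 300,
                       anchors = cofe_anchors()) {
  stopifnot(length(x) == 1L, length(H) == 1L)
  if (length(D) == 0L || length(f) == 0L) {
    abort("empty grid: `D` and `f` must be non-empty.",
          class = "ferroheat_domain_error")
  }
  if (is.unsorted(D, strictly = TRUE) || is.unsorted(f, strictly = TRUE)) {
    abort("grid vectors must be strictly increasing.",
          class = "ferroheat_domain_error")
  }
  grid <- tidyr::expand_grid(D = D, f = f)
  out <- specific_loss_power(x, grid$D, H, grid$f, epsilon, tau0, T, anchors) |>
    select(all_of(c("x", "D", "f", "H", "Ps")))
  class(out) <- c("slp_surface", class(out))
  out
}

#' Maximum loss power across compositions
#'
#' Runs [find_optimal_diameter()] for every requested composition (and
#' frequency, if several are given) and returns the tidy table of
#' `(x, H, f, D_M, PsM)` -- the per-composition optimum summary.
#'
#' @inheritParams find_optimal_diameter
#' @param x Vector of Co2+ concentrations.
#' @param f One or more field frequencies, Hz.
#' @return A tibble with one row per (x, f) combination.
#' @examples
#' psm_vs_x(x = c(0, 1), H = 20e3, f = 100e3)
#' @export
psm_vs_x <- function(x, H, f, D_range = c(1e-9, 20e-9), epsilon = 0.1,
                     tau0 = 1e-9, T = 300, coarse_step = 5e-11, tol = 1e-13,
                     anchors = cofe_anchors()) {
  grid <- tidyr::expand_grid(x = x, f = f)
  purrr::map2(grid$x, grid$f, function(xi_, fi_) {
    tidy(find_optimal_diameter(xi_, H, fi_, D_range, epsilon, tau0, T,
                               coarse_step, tol, anchors))
  }) |>
    bind_rows()
}

#' Optimal diameter as a function of frequency
#'
#' @inheritParams psm_vs_x
#' @return A tibble of `(x, f, H, D_M)`, one row per (x, f).
#' @export
dm_vs_frequency <- function(x, f, H, D_range = c(1e-9, 20e-9), epsilon = 0.1,
                            tau0 = 1e-9, T = 300, coarse_step = 5e-11,
                            tol = 1e-13, anchors = cofe_anchors()) {
  psm_vs_x(x, H, f, D_range, epsilon, tau0, T, coarse_step, tol, anchors) |>
    select(all_of(c("x", "f", "H", "D_M")))
}
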