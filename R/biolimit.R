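# Admissible biological limit: the field amplitude and frequency are not
# free -- safe exposure of healthy tissue caps their product H x f.  Along
# that constraint curve f = C / H the optimal diameter and maximum loss
# power become functions of H alone (per composition).

#' Limit frequency for a field amplitude
#'
#' The admissible field--frequency product constraint `H x f = C` gives the
#' largest safe frequency `f_l = C / H` at amplitude `H`.  The default
#' `limit = 5e9` A Hz/m is the customary safety product for magnetic
#' hyperthermia.
#'
#' @param H Field amplitude, A/m (positive).
#' @param limit Field-frequency product limit `C`, A Hz/m.
#' @return Limit frequency in Hz, vectorized over `H`; the product
#'   `H * limit_frequency(H)` equals `limit` to machine precision.
#' @examples
#' limit_frequency(10e3) / 1e3   # kHz
#' @export
limit_frequency <- function(H, limit = 5e9) {
  check_range(H, "H", 0, lower_open = TRUE)
  check_range(limit, "limit", 0, lower_open = TRUE)
  limit / H
}

#' Optimal operating points on the biological-limit curve
#'
#' For every combination of field amplitude and composition, sets
#' `f_l = limit / H` and maximizes the loss power over the diameter,
#' yielding the limit optimum `(PsM_l, D_Mo)`.
#'
#' @inheritParams psm_vs_x
#' @param H Vector of field amplitudes, A/m.
#' @param limit Field-frequency product limit, A Hz/m.
#' @return A tibble with one row per (H, x): columns `H`, `f_l`, `x`,
#'   `PsM_l` (W/g), `D_Mo` (m).
#' @examples
#' limit_optimum(x = 0, H = 10e3)
#' @export
limit_optimum <- function(x, H, limit = 5e9, D_range = c(1e-9, 20e-9),
                          epsilon = 0.1, tau0 = 1e-9, T = 300,
                          coarse_step = 5e-11, tol = 1e-13,
                          anchors = cofe_anchors()) {
  grid <- tidyr::expand_grid(H = H, x = x)
  purrr::map2(grid$H, grid$x, function(Hi, xi_) {
    fl <- limit_frequency(Hi, limit)
    opt <- find_optimal_diameter(xi_, Hi, fl, D_range, epsilon, tau0, T,
                                 coarse_step, tol, anchors)
    tibble(H = Hi, f_l = fl, x = xi_, PsM_l = opt$PsM, D_Mo = opt$D_M)
  }) |>
    bind_rows()
}

#' Limit loss power versus field amplitude
#'
#' Per-composition curve of the maximum admissible loss power `(PsM)_l`
#' against the field amplitude, with the marginal gain `d(PsM)_l/dH`
#' appended (central differences; one-sided at the grid ends).
#'
#' @inheritParams limit_optimum
#' @return A tibble of `(x, H, f_l, PsM_l, D_Mo, dPsM_dH)` ordered by x
#'   then H.
#' @export
psml_vs_field <- function(x, H, limit = 5e9, D_range = c(1e-9, 20e-9),
                          epsilon = 0.1, tau0 = 1e-9, T = 300,
                          coarse_step = 5e-11, tol = 1e-13,
                          anchors = cofe_anchors()) {
  if (length(H) == 0L) {
    abort("empty field grid.", class = "ferroheat_domain_error")
  }
  limit_optimum(x, H, limit, D_range, epsilon, tau0, T,
                coarse_step, tol, anchors) |>
    arrange(.data$x, .data$H) |>
    group_by(.data$x) |>
    mutate(dPsM_dH = grad_central(.data$H, .data$PsM_l)) |>
    ungroup() |>
    select(all_of(c("x", "H", "f_l", "PsM_l", "D_Mo", "dPsM_dH")))
}

grad_central <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(NA_real_)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Recommended operating window under the biological limit
#'
#' Encodes the operating-window recommendation as an explicit two-rule
#' heuristic on a field-amplitude grid along `f = limit / H`:
#'
#' * lower bound: the smallest `H` whose limit loss power reaches
#'   `threshold` (a therapeutically useful dose, default 10 W/g);
#' * upper bound: capped at `H_cap`, and tightened to the last `H` before
#'   the relative gain per grid step falls below `saturation_rel_gain` --
#'   beyond that point a larger (harder to build) coil buys almost nothing.
#'
#' @inheritParams limit_optimum
#' @param x Single composition in \[0, 1\].
#' @param threshold Minimum acceptable limit loss power, W/g; default 10.
#' @param H_cap Hardware cap on the amplitude, A/m; default 50 kA/m.
#' @param saturation_rel_gain Relative gain per grid step below which the
#'   curve is considered saturated; default 0.05.
#' @param H_grid Field-amplitude grid, A/m; default 10--50 kA/m in 10 kA/m
#'   steps (clipped at `H_cap`).
#' @return A one-row tibble: `x`, `feasible`, `H_lo`, `H_hi` (A/m),
#'   `f_hi`, `f_lo` (Hz; frequencies at `H_lo` and `H_hi` respectively),
#'   and the rationale flags `threshold_met`, `saturation_capped`,
#'   `hardware_capped`.  An unreachable threshold yields
#'   `feasible = FALSE` with `NA` bounds rather than an error.
#' @examples
#' operating_window(x = 0)
#' @export
operating_window <- function(x, limit = 5e9, threshold = 10, H_cap = 50e3,
                             saturation_rel_gain = 0.05,
                             H_grid = seq(10e3, 50e3, by = 10e3),
                             D_range = c(1e-9, 20e-9), epsilon = 0.1,
                             tau0 = 1e-9, T = 300, coarse_step = 5e-11,
                             tol = 1e-13, anchors = cofe_anchors()) {
  stopifnot(length(x) == 1L)
  check_range(threshold, "threshold", 0, lower_open = TRUE)
  H_grid <- sort(H_grid[H_grid <= H_cap])
  if (length(H_grid) == 0L) {
    abort("`H_grid` is empty after applying `H_cap`.",
          class = "ferroheat_domain_error")
  }
  curve <- limit_optimum(x, H_grid, limit, D_range, epsilon, tau0, T,
                         coarse_step, tol, anchors)
  ps <- curve$PsM_l
  ok <- ps >= threshold
  threshold_met <- any(ok)
  if (!threshold_met) {
    return(tibble(x = x, feasible = FALSE,
                  H_lo = NA_real_, H_hi = NA_real_,
                  f_hi = NA_real_, f_lo = NA_real_,
                  threshold_met = FALSE, saturation_capped = FALSE,
                  hardware_capped = FALSE))
  }
  H_lo <- H_grid[which(ok)[1]]
  rel_gain <- c(NA_real_, diff(ps) / ps[-length(ps)])
  weak <- which(rel_gain < saturation_rel_gain)
  if (length(weak) > 0L) {
    H_hi <- H_grid[weak[1] - 1L]
    saturation_capped <- TRUE
  } else {
    H_hi <- H_grid[length(H_grid)]
    saturation_capped <- FALSE
  }
  H_hi <- max(H_hi, H_lo)
  tibble(x = x, feasible = TRUE, H_lo = H_lo, H_hi = H_hi,
         f_hi = limit_frequency(H_lo, limit),
         f_lo = limit_frequency(H_hi, limit),
         threshold_met = TRUE, saturation_capped = saturation_capped,
         hardware_capped = !saturation_capped && H_hi >= H_cap)
}
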