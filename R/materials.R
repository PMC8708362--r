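# Material-property models for the Co(x)Fe(3-x)O4 ferrite series.
#
# The series interpolates between magnetite (x = 0, magnetically soft,
# K = 11 kJ/m3) and cobalt ferrite (x = 1, hard, K = 200 kJ/m3) as Co2+ ions
# replace Fe2+ on octahedral sites.  Anisotropy peaks at 294 kJ/m3 near
# x = 0.67; spontaneous magnetization falls linearly from 480 to 425 kA/m.

.materials_cache <- new.env(parent = emptyenv())

#' Reference anchor table for Co-ferrite material properties
#'
#' Room-temperature anchor values of the magnetocrystalline anisotropy
#' constant `K`, spontaneous magnetization `Ms` and mass density `rho` of
#' Co\eqn{_x}Fe\eqn{_{3-x}}O\eqn{_4} at nine Co\eqn{^{2+}} concentrations.
#' The anisotropy anchors extend to x = 1.1; `Ms` and `rho` are defined on
#' x in \[0, 1\].  The table ships as a plain CSV
#' (`system.file("extdata", "cofe_anchors.csv", package = "ferroheat")`) so
#' that experimentally measured anchors can be substituted.
#'
#' @return A tibble with columns `x` (dimensionless), `K` (J/m3),
#'   `Ms` (A/m) and `rho` (kg/m3); `Ms` and `rho` are `NA` at x = 1.1.
#' @examples
#' cofe_anchors()
#' @export
cofe_anchors <- function() {
  if (is.null(.materials_cache$anchors)) {
    path <- system.file("extdata", "cofe_anchors.csv", package = "ferroheat")
    raw <- utils::read.csv(path)
    .materials_cache$anchors <- tibble(
      x = as.numeric(raw$x), K = as.numeric(raw$K_J_per_m3),
      Ms = as.numeric(raw$Ms_A_per_m), rho = as.numeric(raw$rho_kg_per_m3)
    )
  }
  .materials_cache$anchors
}

check_anchors <- function(anchors) {
  stopifnot(is.data.frame(anchors), all(c("x", "K") %in% names(anchors)))
  if (is.unsorted(anchors$x, strictly = TRUE)) {
    abort("anchor table `x` must be strictly increasing.",
          class = "ferroheat_domain_error")
  }
  anchors
}

#' Magnetocrystalline anisotropy constant K(x)
#'
#' Shape-preserving piecewise-cubic interpolation of the anisotropy anchors:
#' the anchor sequence is split into maximal monotone runs at its interior
#' extrema and each run is interpolated with the monotone Fritsch--Carlson
#' cubic ([stats::splinefun()], `method = "monoH.FC"`).  Exact at every
#' anchor, continuous in between, and cannot overshoot, so the single
#' interior maximum stays at the x = 0.67 anchor.
#'
#' @param x Co2+ concentration(s), dimensionless, in \[0, 1.1\].
#' @param anchors Anchor table as returned by [cofe_anchors()]; substitute
#'   measured values here if available.
#' @return Anisotropy constant in J/m3, vectorized over `x`.
#' @examples
#' anisotropy_constant(c(0, 0.67, 1)) / 1e3   # kJ/m3
#' @export
anisotropy_constant <- function(x, anchors = cofe_anchors()) {
  check_range(x, "x", 0, max(anchors$x))
  check_anchors(anchors)
  key <- paste0("Kfun_", paste(anchors$x, anchors$K, collapse = ";"))
  if (is.null(.materials_cache[[key]])) {
    .materials_cache[[key]] <- shape_preserving_spline(anchors$x, anchors$K)
  }
  .materials_cache[[key]](x)
}

# Monotone-run-wise Fritsch-Carlson interpolant: monoH.FC alone guarantees
# shape only on monotone data, so the anchors are split at interior extrema
# and each monotone run gets its own monotone cubic.  Exact at anchors,
# continuous everywhere, no overshoot past an extremum anchor.
shape_preserving_spline <- function(x, y) {
  n <- length(x)
  dy <- diff(y)
  extremum <- which(dy[-1] * dy[-(n - 1)] < 0) + 1L
  bounds <- c(1L, extremum, n)
  funs <- lapply(seq_len(length(bounds) - 1L), function(k) {
    i <- bounds[k]:bounds[k + 1L]
    splinefun(x[i], y[i], method = "monoH.FC")
  })
  breaks <- x[extremum]
  function(xq) {
    seg <- findInterval(xq, breaks) + 1L
    out <- numeric(length(xq))
    for (k in unique(seg)) {
      sel <- seg == k
      out[sel] <- funs[[k]](xq[sel])
    }
    out
  }
}

#' Spontaneous magnetization Ms(x)
#'
#' Linear variation with Co2+ concentration, fixed by the endpoint values
#' of the anchor table: 480 kA/m for magnetite (x = 0) down to 425 kA/m for
#' cobalt ferrite (x = 1).
#'
#' @inheritParams anisotropy_constant
#' @return Spontaneous magnetization in A/m, vectorized over `x`.
#' @examples
#' spontaneous_magnetization(0.5) / 1e3   # kA/m
#' @export
spontaneous_magnetization <- function(x, anchors = cofe_anchors()) {
  check_range(x, "x", 0, 1)
  ends <- affine_endpoints(anchors, "Ms")
  ends$a + ends$b * x
}

#' Mass density rho(x)
#'
#' Linear through the endpoint anchors: 5.24e3 kg/m3 at x = 0 to
#' 5.29e3 kg/m3 at x = 1; reproduces every intermediate anchor to the
#' tabulated precision.
#'
#' @inheritParams anisotropy_constant
#' @return Density in kg/m3, vectorized over `x`.
#' @export
ferrite_density <- function(x, anchors = cofe_anchors()) {
  check_range(x, "x", 0, 1)
  ends <- affine_endpoints(anchors, "rho")
  ends$a + ends$b * x
}

affine_endpoints <- function(anchors, col) {
  check_anchors(anchors)
  i0 <- which(anchors$x == 0)
  i1 <- which(anchors$x == 1)
  if (length(i0) != 1L || length(i1) != 1L) {
    abort(sprintf("anchor table needs x = 0 and x = 1 rows to fix the %s line.", col),
          class = "ferroheat_domain_error")
  }
  v0 <- anchors[[col]][i0]
  v1 <- anchors[[col]][i1]
  list(a = v0, b = v1 - v0)
}

#' All material properties at a composition
#'
#' Bundles [anisotropy_constant()], [spontaneous_magnetization()] and
#' [ferrite_density()] into one tidy row per composition.
#'
#' @inheritParams anisotropy_constant
#' @return A tibble with columns `x`, `K` (J/m3), `Ms` (A/m), `rho` (kg/m3).
#' @examples
#' material_properties(c(0, 0.2, 0.8))
#' @export
material_properties <- function(x, anchors = cofe_anchors()) {
  check_range(x, "x", 0, 1)
  tibble(
    x   = x,
    K   = anisotropy_constant(x, anchors),
    Ms  = spontaneous_magnetization(x, anchors),
    rho = ferrite_density(x, anchors)
  )
}
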