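# ggplot2 views of the model products.  All plot functions take the tidy
# tables the computation functions return, so they chain with the pipe.

#' Plot a loss-power surface
#'
#' Heat-map of `Ps(D, f)` from [ps_surface()]; the bright ridge marks the
#' optimal-diameter line.
#'
#' @param surface A tibble from [ps_surface()].
#' @return A ggplot object.
#' @export
plot_ps_surface <- function(surface) {
  ggplot2::ggplot(surface,
                  ggplot2::aes(.data$D * 1e9, .data$f / 1e3, fill = .data$Ps)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Ps (W/g)") +
    ggplot2::labs(x = "diameter D (nm)", y = "frequency f (kHz)",
                  title = sprintf("Specific loss power, x = %g, H = %g kA/m",
                                  surface$x[1], surface$H[1] / 1e3))
}

#' @rdname plot_ps_surface
#' @param object An `slp_surface` tibble.
#' @param ... Unused.
#' @method autoplot slp_surface
#' @export
autoplot.slp_surface <- function(object, ...) plot_ps_surface(object)

#' Plot the maximum loss power across compositions
#'
#' @param optima A tibble from [psm_vs_x()] (several frequencies allowed).
#' @return A ggplot object.
#' @export
plot_psm_vs_x <- function(optima) {
  ggplot2::ggplot(optima, ggplot2::aes(.data$x, .data$PsM,
                                       colour = factor(.data$f / 1e3))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Co concentration x", y = "PsM (W/g)",
                  colour = "f (kHz)")
}

#' Plot the bio-limit loss power against field amplitude
#'
#' @param curve A tibble from [psml_vs_field()].
#' @return A ggplot object.
#' @export
plot_psml_vs_field <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$H / 1e3, .data$PsM_l,
                                      colour = factor(.data$x))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "H (kA/m)", y = "(PsM)_l (W/g)", colour = "x")
}

#' @describeIn find_optimal_diameter Loss-power curve around the optimum
#'   with the maximum marked.
#' @param object An `slp_optimum` object.
#' @method autoplot slp_optimum
#' @export
autoplot.slp_optimum <- function(object, ...) {
  p <- object$params
  D <- seq(p$D_range[1], p$D_range[2], length.out = 400)
  curve <- specific_loss_power(object$x, D, object$H, object$f,
                               p$epsilon, p$tau0, p$T)
  ggplot2::ggplot(curve, ggplot2::aes(.data$D * 1e9, .data$Ps)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$D_M * 1e9, y = object$PsM,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "diameter D (nm)", y = "Ps (W/g)",
                  title = sprintf("x = %g, H = %g kA/m, f = %g kHz: D_M = %.1f nm",
                                  object$x, object$H / 1e3, object$f / 1e3,
                                  object$D_M * 1e9))
}
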