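# ggplot2 autoplot methods for the result types.

#' Plot a scattering curve
#'
#' Log-intensity versus q, with an error ribbon when sigma is present.
#'
#' @param curve scattering-curve tibble.
#' @return a ggplot object.
#' @export
plot_saxs_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)")
  if ("sigma" %in% names(curve)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$I - .data$sigma, .Machine$double.xmin),
                   ymax = .data$I + .data$sigma),
      alpha = 0.3
    )
  }
  p
}

#' @method autoplot guinier_fit
#' @export
autoplot.guinier_fit <- function(object, curve = NULL, ...) {
  if (is.null(curve)) abort("pass the fitted curve via `curve =`")
  df <- tibble(q2 = curve$q^2, lnI = log(pmax(curve$I, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q2, y = .data$lnI)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(intercept = log(object$i0),
                         slope = -object$rg^2 / 3, colour = "red") +
    ggplot2::geom_vline(xintercept = object$q_max^2, linetype = 2) +
    ggplot2::labs(x = expression(q^2), y = "ln I(q)",
                  title = sprintf("Guinier fit: Rg = %.2f Å", object$rg))
}

#' Dimensionless Kratky plot with reference shapes
#'
#' @param kratky output of [kratky_dimensionless()].
#' @export
plot_kratky <- function(kratky) {
  ggplot2::ggplot(kratky, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ref_globular), linetype = 2,
                       colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ref_coil), linetype = 3,
                       colour = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 3)) +
    ggplot2::labs(x = expression(qR[g]),
                  y = expression((qR[g])^2 ~ I(q) / I(0)))
}

#' @method autoplot pair_distribution
#' @export
autoplot.pair_distribution <- function(object, ...) {
  ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$r, y = .data$P)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "P(r)",
                  title = sprintf("Dmax = %.1f Å", object$dmax))
}

#' @method autoplot maxpars_posterior
#' @export
autoplot.maxpars_posterior <- function(object, ...) {
  s <- summarize_weights(object)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$member), y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                        ymax = pmin(.data$mean + .data$sd, 1)),
                           width = 0.3) +
    ggplot2::labs(x = "basis-set member", y = "posterior weight")
}

#' @method autoplot maxent_lcurve
#' @export
autoplot.maxent_lcurve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$s_kl, y = .data$chi2_red)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$curve[object$curve$theta == object$selected_theta, ],
                        colour = "red", size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(S[KL]), y = expression(chi[red]^2))
}

#' @method autoplot free_energy_surface
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  df <- tidy.free_energy_surface(object)
  ggplot2::ggplot(df[!is.na(df$free_energy), ],
                  ggplot2::aes(x = .data$cv1, y = .data$cv2,
                               fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0("F (", object$units, ")")) +
    ggplot2::labs(x = "CV1 (Å)", y = "CV2 (Å)")
}
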