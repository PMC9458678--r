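# broom-style tidiers for the fitted objects.

#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble(
    term = c("rg", "i0"),
    estimate = c(x$rg, x$i0),
    std.error = c(x$rg_se, x$i0_se)
  )
}

#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(rg = x$rg, i0 = x$i0, q_min = x$q_min, q_max = x$q_max,
         qrg_max = x$qrg_max, n_points = x$n_points)
}

#' @export
tidy.saxs_fit <- function(x, ...) {
  tibble(term = c("scale", "constant"), estimate = c(x$c, x$constant))
}

#' @export
glance.saxs_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, chi2_red = x$chi2_red, n_points = x$n_points)
}

#' @export
tidy.pair_distribution <- function(x, ...) x$pr

#' @export
glance.pair_distribution <- function(x, ...) {
  tibble(dmax = x$dmax, rg_pr = x$rg_pr, bin_width = x$bin_width)
}

#' @export
tidy.maxpars_posterior <- function(x, ...) {
  s <- summarize_weights(x)
  tibble(member = s$member, estimate = s$mean, std.error = s$sd)
}

#' @export
glance.maxpars_posterior <- function(x, ...) {
  tibble(k = ncol(x$samples), samples = nrow(x$samples),
         acceptance = x$acceptance, steps = x$steps, burn = x$burn,
         seed = x$seed)
}

#' @export
tidy.maxent_fit <- function(x, ...) {
  tibble(member = seq_along(x$weights), weight = x$weights, w0 = x$w0)
}

#' @export
glance.maxent_fit <- function(x, ...) {
  tibble(theta = x$theta, s_kl = x$s_kl, chi2 = x$chi2,
         chi2_red = x$chi2_red, scale = x$scale,
         iterations = x$iterations, converged = x$converged)
}

#' @export
tidy.maxent_lcurve <- function(x, ...) x$curve

#' @export
glance.maxent_lcurve <- function(x, ...) {
  tibble(n_theta = nrow(x$curve), selected_theta = x$selected_theta,
         chi2_red = x$selected$chi2_red, s_kl = x$selected$s_kl)
}

#' @export
tidy.free_energy_surface <- function(x, ...) {
  c1 <- (x$edges1[-1] + x$edges1[-length(x$edges1)]) / 2
  c2 <- (x$edges2[-1] + x$edges2[-length(x$edges2)]) / 2
  grid <- expand.grid(cv1 = c1, cv2 = c2)
  tibble(cv1 = grid$cv1, cv2 = grid$cv2, free_energy = as.vector(x$F))
}
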