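#' Guinier analysis of a scattering curve
#'
#' Weighted linear regression of \eqn{\ln I} on \eqn{q^2} over the low-q
#' Guinier region, where \eqn{I(q) \approx I(0) \exp(-q^2 R_g^2/3)} for
#' globular particles, giving \eqn{R_g = \sqrt{-3\,\mathrm{slope}}}. The fit
#' window starts from the lowest 20 usable points (positive I, the first
#' non-positive intensity truncates the range) and is grown/shrunk
#' iteratively until \eqn{q_{max} R_g \le} `qrg_limit`.
#'
#' @param curve scattering-curve tibble (`q`, `I`, optional `sigma`).
#' @param qrg_limit upper validity limit for \eqn{q R_g} (conventional 1.3).
#' @return a `guinier_fit` object: `rg`, `i0`, their standard errors, the q
#'   window and point count.
#' @export
guinier_fit <- function(curve, qrg_limit = 1.3) {
  usable <- which(curve$q > 0)
  bad <- which(curve$I <= 0)
  if (length(bad) > 0) usable <- usable[usable < min(bad)]
  if (length(usable) < 5) abort("fewer than 5 usable points for Guinier fit")
  q2 <- curve$q[usable]^2
  y <- log(curve$I[usable])
  wts <- if ("sigma" %in% names(curve)) (curve$I[usable] / curve$sigma[usable])^2 else rep(1, length(y))

  m <- min(20L, length(usable))
  fit_window <- function(m) {
    ii <- seq_len(m)
    f <- lm(y ~ q2, subset = ii, weights = wts)
    slope <- coef(f)[[2]]
    list(fit = f, slope = slope,
         rg = if (slope <= 0) sqrt(-3 * slope) else NA_real_)
  }
  for (iter in 1:50) {
    fw <- fit_window(m)
    if (is.na(fw$rg)) {
      if (fw$slope < 1e-10) fw$rg <- 0 else abort("positive Guinier slope: no Guinier region")
    }
    m_new <- if (fw$rg == 0) length(usable) else {
      max(5L, sum(curve$q[usable] <= qrg_limit / fw$rg))
    }
    m_new <- min(m_new, length(usable))
    if (m_new == m) break
    m <- m_new
  }
  # exact synthetic curves trigger lm's "essentially perfect fit" caution,
  # which is the expected situation here, not a defect
  sm <- suppressWarnings(summary(fw$fit))$coefficients
  slope <- fw$slope
  rg <- fw$rg
  if (rg > 0 && rg * curve$q[usable][m] < 1e-6) rg <- 0  # numerically flat
  i0 <- exp(coef(fw$fit)[[1]])
  rg_se <- if (rg > 0) 3 * sm[2, 2] / (2 * rg) else NA_real_
  structure(
    list(rg = rg, i0 = i0, rg_se = rg_se, i0_se = i0 * sm[1, 2],
         q_min = curve$q[usable][1], q_max = curve$q[usable][m],
         n_points = m, qrg_max = curve$q[usable][m] * rg,
         qrg_limit = qrg_limit),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.3f +/- %.3f A, I(0) = %.4g (%d pts, qRg_max = %.2f)\n",
              x$rg, x$rg_se, x$i0, x$n_points, x$qrg_max))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Transforms a curve to \eqn{(x, y) = (qR_g, (qR_g)^2 I(q)/I(0))} using a
#' Guinier fit for the normalisation, together with the two reference shapes:
#' the globular (Guinier-law) curve \eqn{f(x) = x^2 \exp(-x^2/3)}, which
#' peaks at \eqn{(\sqrt 3, 3/e)}, and the Gaussian-coil (Debye) curve
#' \eqn{f(x) = 2/x^2\,[\exp(-x^2) + x^2 - 1]}. Deviation of the measured
#' transform from the globular bell towards the coil plateau diagnoses
#' interdomain flexibility.
#'
#' @param curve scattering-curve tibble.
#' @param fit a [guinier_fit()] result for the same curve.
#' @return tibble with `x`, `y`, `ref_globular`, `ref_coil`.
#' @export
kratky_dimensionless <- function(curve, fit) {
  if (fit$i0 <= 0) abort("Guinier I(0) must be positive")
  x <- curve$q * fit$rg
  y <- x^2 * curve$I / fit$i0
  tibble(
    x = x, y = y,
    ref_globular = kratky_reference_globular(x),
    ref_coil = kratky_reference_coil(x)
  )
}

#' @rdname kratky_dimensionless
#' @param x dimensionless \eqn{qR_g} values.
#' @export
kratky_reference_globular <- function(x) x^2 * exp(-x^2 / 3)

#' @rdname kratky_dimensionless
#' @export
kratky_reference_coil <- function(x) {
  ifelse(x == 0, 0, 2 / x^2 * (exp(-x^2) + x^2 - 1))
}

#' Model-based pair-distance distribution P(r)
#'
#' Histogram of all pairwise scatterer distances of a conformer, weighted by
#' the zero-angle form factors \eqn{f_i(0) f_j(0)} and normalised to unit
#' area. Dmax is the maximum pairwise distance. The distribution radius of
#' gyration uses the total-weight normalisation
#' \eqn{R_g^2 = \sum_{i<j} w_i w_j r_{ij}^2 / (\sum_i w_i)^2}, which equals
#' the (f-weighted) geometric radius of gyration exactly, also for few-atom
#' systems.
#'
#' @param conf conformer tibble (>= 2 scatterers).
#' @param bin_width histogram bin width in Angstrom.
#' @param form_factor_model as in [debye_curve()].
#' @return a `pair_distribution` object: tibble `pr` (`r` bin centers, `P`),
#'   `dmax`, `rg_pr`.
#' @export
pr_from_model <- function(conf, bin_width = 1, form_factor_model = "unit") {
  if (nrow(conf) < 2) abort("P(r) needs at least 2 scatterers")
  w <- if (form_factor_model == "unit") rep(1, nrow(conf))
       else form_factor_matrix(conf$element, 0, form_factor_model)[1, ]
  d <- as.vector(dist(as.matrix(conf[, c("x", "y", "z")])))
  unit_w <- all(w == 1)
  if (unit_w) {
    pw <- rep(1, length(d))
  } else {
    # pair weights in the same (column-major lower-triangle) order as dist()
    pw <- tcrossprod(w)[lower.tri(diag(length(w)))]
  }
  dmax <- max(d)
  breaks <- seq(0, max(bin_width, ceiling(dmax / bin_width) * bin_width), by = bin_width)
  nb <- length(breaks) - 1L
  bin <- pmin(pmax(ceiling(d / bin_width), 1L), nb)
  if (unit_w) {
    counts <- tabulate(bin, nbins = nb)
  } else {
    counts <- numeric(nb)
    agg <- rowsum(pw, bin)
    counts[as.integer(rownames(agg))] <- agg
  }
  P <- counts / (sum(pw) * bin_width)
  rg_pr <- sqrt(sum(pw * d^2) / sum(w)^2)
  structure(
    list(pr = tibble(r = (breaks[-1] + breaks[-length(breaks)]) / 2, P = P),
         dmax = dmax, rg_pr = rg_pr, bin_width = bin_width),
    class = "pair_distribution"
  )
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("P(r): %d bins of %.2f A, Dmax = %.2f A, Rg(P(r)) = %.2f A\n",
              nrow(x$pr), x$bin_width, x$dmax, x$rg_pr))
  invisible(x)
}
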