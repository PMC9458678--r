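# Maximum-entropy ensemble reweighting: minimisation of the KL-regularized
# negative log-posterior L(w) = theta * S_KL(w | w0) + chi2(w)/2 over the
# weight simplex, a theta scan with warm starts, L-curve elbow selection,
# and extraction of significantly up-weighted conformers.

#' Kullback-Leibler divergence between weight vectors
#'
#' \eqn{S_{KL} = \sum_k w_k \ln(w_k / w^0_k)}, with \eqn{0 \ln 0 = 0}.
#' Non-negative, and zero iff the two distributions coincide.
#'
#' @param w,w0 weight vectors on the simplex (optimised and reference).
#' @return non-negative scalar.
#' @export
kl_divergence <- function(w, w0) {
  check_simplex(w); check_simplex(w0)
  if (length(w) != length(w0)) abort("weight vectors differ in length")
  if (any(w > 0 & w0 == 0)) abort("infinite divergence: w places mass where w0 is zero")
  nz <- w > 0
  sum(w[nz] * log(w[nz] / w0[nz]))
}

#' Negative log-posterior of the maximum-entropy model
#'
#' \eqn{L = \theta\, S_{KL}(w\,\|\,w^0) + \chi^2(w)/2}, where the
#' chi-squared uses the ensemble-average profile \eqn{\sum_k w_k I_k} and a
#' multiplicative nuisance scale (profiled by its closed form unless given).
#' Constant factors in the chi-squared convention only rescale \eqn{\theta}.
#'
#' @param w weights on the simplex.
#' @param theta confidence parameter (>= 0); large theta pins w to w0.
#' @param profiles list of per-conformer scattering curves on the
#'   experimental grid.
#' @param exp_curve experimental curve with `sigma`.
#' @param w0 reference weights (default uniform).
#' @param scale fixed nuisance scale c, or `NULL` for the closed form.
#' @return scalar L.
#' @export
neg_log_posterior <- function(w, theta, profiles, exp_curve, w0 = NULL,
                              scale = NULL) {
  K <- length(w)
  if (is.null(w0)) w0 <- rep(1 / K, K)
  st <- chi2_stats(profiles, exp_curve)
  chi2 <- if (is.null(scale)) {
    chi2_from_stats(w, st)
  } else {
    bw <- as.vector(st$B %*% w)
    st$C - 2 * scale * sum(st$A * w) + scale^2 * sum(w * bw)
  }
  theta * kl_divergence(w, w0) + chi2 / 2
}

softmax <- function(g) {
  e <- exp(g - max(g))
  e / sum(e)
}

#' Maximum-entropy weight optimisation at one theta
#'
#' Minimises the negative log-posterior over the simplex by quasi-Newton
#' (BFGS) optimisation in unconstrained log-weight coordinates (softmax
#' back-transform) with the analytic gradient, alternating with closed-form
#' re-estimation of the nuisance scale for `outer_iterations` rounds.
#' Convergence is declared when the relative change of L drops below 1e-10.
#'
#' @inheritParams neg_log_posterior
#' @param outer_iterations rounds of weight optimisation alternated with
#'   scale re-estimation (default 10).
#' @param fit_scale profile a multiplicative scale c (default TRUE).
#' @param w_init optional warm-start weights.
#' @return a `maxent_fit` object: `theta`, `weights`, `w0`, `s_kl`, `chi2`,
#'   `chi2_red`, `scale`, `iterations`, `converged`.
#' @export
optimize_weights <- function(theta, w0, profiles, exp_curve,
                             outer_iterations = 10, fit_scale = TRUE,
                             w_init = NULL) {
  if (theta < 0) abort("theta must be non-negative")
  st <- chi2_stats(profiles, exp_curve)
  K <- st$K
  if (is.null(w0)) w0 <- rep(1 / K, K)
  if (length(w0) != K) abort("w0 length must match the number of profiles")
  check_simplex(w0)
  if (any(w0 <= 0)) abort("reference weights must be strictly positive")
  if (K < 2) abort("need at least 2 profiles")

  w <- if (is.null(w_init)) w0 else w_init
  cc <- if (fit_scale) {
    bw <- as.vector(st$B %*% w)
    sum(st$A * w) / sum(w * bw)
  } else 1

  klterm <- function(w) {
    nz <- w > 0
    sum(w[nz] * log(w[nz] / w0[nz]))
  }
  # with fit_scale the scale is profiled by its closed form at every
  # evaluation (the envelope theorem leaves the chi2 gradient unchanged at
  # the profiled c); the outer rounds below re-estimate and confirm it
  scale_at <- function(w, bw, cc) {
    if (fit_scale) sum(st$A * w) / sum(w * bw) else cc
  }
  obj <- function(g, cc) {
    w <- softmax(g)
    bw <- as.vector(st$B %*% w)
    cc <- scale_at(w, bw, cc)
    chi2 <- st$C - 2 * cc * sum(st$A * w) + cc^2 * sum(w * bw)
    theta * klterm(w) + chi2 / 2
  }
  grad <- function(g, cc) {
    w <- softmax(g)
    bw <- as.vector(st$B %*% w)
    cc <- scale_at(w, bw, cc)
    v <- theta * (log(pmax(w, 1e-300) / w0) + 1) + cc^2 * bw - cc * st$A
    w * (v - sum(w * v))
  }

  g <- log(pmax(w, 1e-300))
  L_prev <- Inf
  converged <- FALSE
  iters <- 0L
  run_bfgs <- function(g, cc) {
    # damp the first quasi-Newton step to O(1) in log-weight coordinates;
    # an undamped step of size |grad| can jump to a simplex vertex, where
    # the softmax parameterisation has a spurious stationary point
    g0_norm <- sqrt(sum(grad(g, cc)^2))
    ps <- rep(1 / sqrt(max(1, g0_norm)), length(g))
    opt <- optim(g, fn = obj, gr = grad, cc = cc, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14, parscale = ps))
    w_opt <- softmax(opt$par)
    if (max(w_opt) > 1 - 1e-9) {
      # vertex escape: restart from a pull-back towards the reference
      g_mid <- log(pmax(0.5 * w_opt + 0.5 * w0, 1e-300))
      ps2 <- ps / 10
      opt2 <- optim(g_mid, fn = obj, gr = grad, cc = cc, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14, parscale = ps2))
      if (opt2$value < opt$value) opt <- opt2
    }
    opt
  }
  for (round in seq_len(outer_iterations)) {
    opt <- run_bfgs(g, cc)
    g <- opt$par
    w <- softmax(g)
    if (fit_scale) {
      bw <- as.vector(st$B %*% w)
      cc <- sum(st$A * w) / sum(w * bw)
    }
    L <- obj(g, cc)
    iters <- round
    if (is.finite(L_prev) && abs(L_prev - L) <= 1e-10 * max(1, abs(L_prev))) {
      converged <- TRUE
      break
    }
    L_prev <- L
  }
  bw <- as.vector(st$B %*% w)
  chi2 <- st$C - 2 * cc * sum(st$A * w) + cc^2 * sum(w * bw)
  structure(
    list(theta = theta, weights = w, w0 = w0,
         s_kl = klterm(w), chi2 = chi2, chi2_red = chi2 / st$n,
         scale = cc, iterations = iters, converged = converged),
    class = "maxent_fit"
  )
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf(
    "MaxEnt fit: theta = %.4g, S_KL = %.4g, chi2_red = %.4g (K = %d, %s)\n",
    x$theta, x$s_kl, x$chi2_red, length(x$weights),
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Scan theta and select the L-curve elbow
#'
#' Runs [optimize_weights()] over a grid of confidence parameters (scanned
#' from the largest theta downwards, each solution warm-starting the next)
#' and selects the elbow of the (S_KL, chi2_red) L-curve as the
#' maximum-curvature point in log-log coordinates. The elbow balances the
#' improvement of the fit against the entropic cost of biasing the
#' reference ensemble.
#'
#' @inheritParams optimize_weights
#' @param theta_grid positive theta values (default 13 log-spaced points,
#'   1e-2 to 1e6).
#' @param theta_select explicit theta overriding the elbow choice.
#' @return a `maxent_lcurve` object: tibble `curve` (`theta`, `s_kl`,
#'   `chi2_red`), list `fits`, `selected_theta`, `selected` fit.
#' @export
theta_scan <- function(profiles, exp_curve, w0 = NULL,
                       theta_grid = 10^seq(-2, 6, length.out = 13),
                       outer_iterations = 10, fit_scale = TRUE,
                       theta_select = NULL) {
  if (any(theta_grid <= 0)) abort("theta grid must be positive")
  theta_grid <- sort(theta_grid)
  K <- length(profiles)
  if (is.null(w0)) w0 <- rep(1 / K, K)
  fits <- vector("list", length(theta_grid))
  w_start <- NULL
  for (i in rev(seq_along(theta_grid))) {
    fits[[i]] <- optimize_weights(theta_grid[i], w0, profiles, exp_curve,
                                  outer_iterations = outer_iterations,
                                  fit_scale = fit_scale, w_init = w_start)
    w_start <- fits[[i]]$weights
  }
  curve <- tibble(
    theta = theta_grid,
    s_kl = map_dbl(fits, "s_kl"),
    chi2_red = map_dbl(fits, "chi2_red")
  )
  sel_theta <- if (!is.null(theta_select)) {
    theta_select
  } else {
    curve$theta[select_elbow(curve$s_kl, curve$chi2_red)]
  }
  sel_i <- which.min(abs(log(curve$theta) - log(sel_theta)))
  structure(
    list(curve = curve, fits = fits,
         selected_theta = curve$theta[sel_i], selected = fits[[sel_i]]),
    class = "maxent_lcurve"
  )
}

#' @rdname theta_scan
#' @param s_kl,chi2_red coordinates of the L-curve points, in theta order.
#' @return [select_elbow()]: the index of the maximum-curvature point.
#' @export
select_elbow <- function(s_kl, chi2_red) {
  n <- length(s_kl)
  if (n == 1) return(1L)
  if (n == 2) return(2L)
  floor_s <- max(s_kl, 1e-12) * 1e-10
  x <- log(pmax(s_kl, floor_s))
  y <- log(pmax(chi2_red, 1e-300))
  ii <- 2:(n - 1)
  xp <- (x[ii + 1] - x[ii - 1]) / 2
  yp <- (y[ii + 1] - y[ii - 1]) / 2
  xpp <- x[ii + 1] - 2 * x[ii] + x[ii - 1]
  ypp <- y[ii + 1] - 2 * y[ii] + y[ii - 1]
  kappa <- abs(xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  kappa[!is.finite(kappa)] <- -Inf
  as.integer(ii[which.max(kappa)])
}

#' @export
print.maxent_lcurve <- function(x, ...) {
  cat(sprintf("MaxEnt L-curve: %d theta values, selected theta = %.4g (chi2_red = %.4g)\n",
              nrow(x$curve), x$selected_theta, x$selected$chi2_red))
  invisible(x)
}

#' Significantly up-weighted conformers
#'
#' Conformers whose optimised weight exceeds the mean weight by more than
#' one (population) standard deviation.
#'
#' @param w weight vector.
#' @return integer indices (possibly empty; uniform weights select none).
#' @export
significant_conformers <- function(w) {
  if (length(w) < 2) abort("need at least 2 weights")
  mu <- mean(w)
  sdev <- sqrt(mean((w - mu)^2))
  which(w > mu + sdev)
}
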