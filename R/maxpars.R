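# Maximum-parsimony weight inference: Bayesian Metropolis Monte Carlo over
# basis-set weights on the probability simplex, targeting the posterior
# P(w | data) propto exp(-chi2(w)) under a uniform simplex prior, with the
# multiplicative scale c profiled out by its closed form at every
# evaluation.

basis_profile_matrix <- function(basis, exp_curve) {
  profiles <- if (inherits(basis, "basis_set")) basis$profiles else basis
  q0 <- exp_curve$q
  Imat <- vapply(profiles, function(p) {
    if (length(p$q) != length(q0) || any(abs(p$q - q0) > 1e-10)) {
      abort("basis profiles and experimental curve must share one q grid")
    }
    p$I
  }, numeric(length(q0)))
  if (length(q0) == 1) Imat <- matrix(Imat, nrow = 1)
  Imat
}

# Sufficient statistics for chi2(w) = C - (A.w)^2 / (w'Bw) with c profiled.
chi2_stats <- function(basis, exp_curve) {
  Imat <- basis_profile_matrix(basis, exp_curve)
  sig <- if ("sigma" %in% names(exp_curve)) exp_curve$sigma else NULL
  if (is.null(sig)) abort("experimental curve lacks sigma")
  if (any(sig <= 0)) abort("sigma must be positive")
  sw <- Imat / sig
  list(
    A = as.vector(crossprod(sw, exp_curve$I / sig)),
    B = crossprod(sw),
    C = sum((exp_curve$I / sig)^2),
    n = length(sig), K = ncol(Imat)
  )
}

#' Chi-squared of a weighted basis-set fit
#'
#' \eqn{\chi^2(w) = \sum_q [(I_{exp} - c\,I_{comp}(w,q))/\sigma_{exp}]^2}
#' with \eqn{I_{comp}(w,q) = \sum_k w_k I_k(q)} and the scaling constant c
#' re-estimated by its weighted least-squares closed form at every
#' evaluation.
#'
#' @param w weight vector on the simplex.
#' @param basis a `basis_set` or list of profile tibbles.
#' @param exp_curve experimental scattering-curve tibble with `sigma`.
#' @return non-negative chi-squared value.
#' @export
chi2_of_weights <- function(w, basis, exp_curve) {
  check_simplex(w)
  st <- chi2_stats(basis, exp_curve)
  chi2_from_stats(w, st)
}

chi2_from_stats <- function(w, st) {
  bw <- as.vector(st$B %*% w)
  denom <- sum(w * bw)
  if (denom <= 0) abort("degenerate basis: zero computed intensity")
  max(st$C - sum(st$A * w)^2 / denom, 0)
}

#' Sample the posterior over basis-set weights
#'
#' Metropolis sampling on the K-simplex with the symmetric transfer
#' proposal: two components are picked uniformly and an amount
#' delta ~ Uniform(-s, s) is moved between them; moves leaving the simplex
#' are rejected. The step size s is tuned during burn-in towards a 25-45%
#' acceptance rate, then frozen.
#'
#' @param basis `basis_set` or list of profiles.
#' @param exp_curve experimental curve with `sigma`.
#' @param steps total Metropolis steps (protocol default 51,000).
#' @param burn initial steps discarded as burn-in (default 1,000).
#' @param seed RNG seed recorded in the output.
#' @param step_size initial transfer half-width.
#' @return a `maxpars_posterior` object: `samples` ((steps-burn) x K),
#'   `acceptance`, `burn`, `steps`, `seed`, `step_size`.
#' @export
sample_posterior <- function(basis, exp_curve, steps = 51000, burn = 1000,
                             seed = 1L, step_size = 0.1) {
  st <- chi2_stats(basis, exp_curve)
  K <- st$K
  if (!is.null(seed)) set.seed(seed)
  S <- steps - burn
  if (S < 1) abort("steps must exceed burn")
  if (K == 1) {
    return(structure(
      list(samples = matrix(1, S, 1), acceptance = 1, burn = burn,
           steps = steps, seed = seed, step_size = step_size),
      class = "maxpars_posterior"
    ))
  }
  w <- rep(1 / K, K)
  log_target <- function(w) -chi2_from_stats(w, st)
  lt <- log_target(w)
  if (!is.finite(lt)) abort("non-finite likelihood at the initial weights")
  s <- step_size
  samples <- matrix(NA_real_, S, K)
  acc_post <- 0L
  acc_win <- 0L
  win <- 0L
  for (t in seq_len(steps)) {
    ij <- sample.int(K, 2)
    delta <- runif(1, -s, s)
    w_new <- w
    w_new[ij[1]] <- w[ij[1]] + delta
    w_new[ij[2]] <- w[ij[2]] - delta
    ok <- w_new[ij[1]] >= 0 && w_new[ij[1]] <= 1 &&
      w_new[ij[2]] >= 0 && w_new[ij[2]] <= 1
    accepted <- FALSE
    if (ok) {
      lt_new <- log_target(w_new)
      if (log(runif(1)) < lt_new - lt) {
        w <- w_new
        lt <- lt_new
        accepted <- TRUE
      }
    }
    if (t <= burn) {
      acc_win <- acc_win + accepted
      win <- win + 1L
      if (win == 100L) {
        rate <- acc_win / win
        if (rate < 0.25) s <- max(s * 0.8, 1e-4)
        if (rate > 0.45) s <- min(s * 1.25, 1)
        acc_win <- 0L; win <- 0L
      }
    } else {
      samples[t - burn, ] <- w
      acc_post <- acc_post + accepted
    }
  }
  structure(
    list(samples = samples, acceptance = acc_post / S, burn = burn,
         steps = steps, seed = seed, step_size = s),
    class = "maxpars_posterior"
  )
}

#' Posterior summary of sampled weights
#'
#' Columnwise mean and standard deviation of the sampled weight vectors; the
#' mean is renormalised onto the simplex.
#'
#' @param samples a `maxpars_posterior` object (or S x K matrix).
#' @return tibble with `member`, `mean`, `sd`.
#' @export
summarize_weights <- function(samples) {
  m <- if (inherits(samples, "maxpars_posterior")) samples$samples else samples
  if (nrow(m) < 2) abort("need at least 2 posterior samples")
  mu <- colMeans(m)
  mu <- mu / sum(mu)
  tibble(member = seq_len(ncol(m)), mean = mu, sd = apply(m, 2, sd))
}

#' @export
print.maxpars_posterior <- function(x, ...) {
  s <- summarize_weights(x)
  cat(sprintf("MaxPars posterior: K = %d, %d samples (%.0f%% acceptance)\n",
              ncol(x$samples), nrow(x$samples), 100 * x$acceptance))
  cat("  mean weights:", paste(sprintf("%.3f", s$mean), collapse = " "), "\n")
  invisible(x)
}
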