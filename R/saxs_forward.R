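#' Theoretical scattering by the Debye equation
#'
#' Computes the orientation-averaged scattering intensity of a conformer as
#' the exact Debye double sum
#' \deqn{I(q) = \sum_i \sum_j f_i(q) f_j(q) \frac{\sin(q r_{ij})}{q r_{ij}},}
#' with the \eqn{i=j} and \eqn{q=0} singularities taken at their analytic
#' limit 1, so that \eqn{I(0) = (\sum_i f_i(0))^2}. Form-factor models:
#' `"unit"` (every scatterer contributes 1; toy bead ensembles with exact
#' analytic oracles), `"residue"` (one bead per residue at its C-alpha,
#' weighted by the residue's electron count) and `"atomic"` (four-Gaussian
#' Cromer-Mann atomic form factors). No hydration-shell term is included;
#' the multiplicative scale of the experiment is absorbed by the fitted
#' scaling constant in [fit_to_experiment()].
#'
#' @param conf conformer tibble.
#' @param q momentum-transfer grid in 1/Angstrom (\eqn{q = 4\pi\sin\theta/\lambda}),
#'   non-negative, increasing.
#' @param form_factor_model `"unit"`, `"residue"` or `"atomic"`.
#' @return a scattering-curve tibble with columns `q`, `I`.
#' @export
debye_curve <- function(conf, q, form_factor_model = c("unit", "residue", "atomic")) {
  form_factor_model <- match.arg(form_factor_model)
  if (nrow(conf) < 1) abort("empty conformer")
  if (any(q < 0)) abort("negative q values")
  if (form_factor_model == "residue") {
    conf <- conf[conf$atom == "CA" | !duplicated(paste(conf$chain, conf$resid)), ]
    conf <- conf[!duplicated(paste(conf$chain, conf$resid)), ]
    fmat <- matrix(residue_electron_count(conf$resname), nrow = length(q),
                   ncol = nrow(conf), byrow = TRUE)
  } else {
    fmat <- form_factor_matrix(conf$element, q, form_factor_model)
  }
  co <- as.matrix(conf[, c("x", "y", "z")])
  n <- nrow(co)
  if (n == 1) {
    return(tibble(q = q, I = fmat[, 1]^2))
  }
  d <- as.vector(dist(co))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  I <- vapply(seq_along(q), function(k) {
    f <- fmat[k, ]
    qd <- q[k] * d
    sinc <- ifelse(qd == 0, 1, sin(qd) / qd)
    sum(f^2) + 2 * sum(f[pairs[, 1]] * f[pairs[, 2]] * sinc)
  }, numeric(1))
  tibble(q = q, I = I)
}

#' Weighted average of scattering profiles
#'
#' Pointwise convex combination \eqn{I(w, q) = \sum_k w_k I_k(q)} of profiles
#' sharing one q grid.
#'
#' @param weights numeric weights, non-negative, summing to 1 (within 1e-8).
#' @param profiles list of scattering-curve tibbles on a common grid.
#' @return scattering-curve tibble.
#' @export
weighted_average_profile <- function(weights, profiles) {
  if (length(weights) != length(profiles)) abort("one weight per profile required")
  check_simplex(weights)
  q0 <- profiles[[1]]$q
  for (p in profiles[-1]) {
    if (length(p$q) != length(q0) || any(abs(p$q - q0) > 1e-10)) {
      abort("profiles must share one q grid")
    }
  }
  Imat <- vapply(profiles, function(p) p$I, numeric(length(q0)))
  if (length(q0) == 1) Imat <- matrix(Imat, nrow = 1)
  tibble(q = q0, I = as.vector(Imat %*% weights))
}

check_simplex <- function(w, tol = 1e-8) {
  if (any(w < -tol)) abort("weights must be non-negative")
  if (abs(sum(w) - 1) > tol) abort("weights must sum to 1")
  invisible(w)
}

#' Fit a computed curve to an experimental curve
#'
#' Weighted least-squares fit of a computed profile to experimental data on a
#' shared q grid. Without a constant, the scale is the closed form
#' \deqn{c = \left[\sum I_{exp} I_{comp}/\sigma^2\right]
#'   \left[\sum I_{comp}^2/\sigma^2\right]^{-1};}
#' with `fit_constant = TRUE` the pair (c, constant) solves the two-parameter
#' weighted normal equations (constant subtraction absorbs buffer-mismatch
#' systematics). Goodness of fit is
#' \eqn{\chi^2 = \sum [(I_{exp} - c I_{comp} - const)/\sigma]^2} and the
#' reduced form \eqn{\chi^2_{red} = \chi^2/N} over the N grid points.
#'
#' @param computed,experimental scattering-curve tibbles on one q grid; the
#'   experimental curve must carry positive `sigma`.
#' @param fit_constant also fit an additive offset.
#' @return a `saxs_fit` list: `c`, `constant`, `chi2`, `chi2_red`, `n_points`.
#' @export
fit_to_experiment <- function(computed, experimental, fit_constant = FALSE) {
  if (length(computed$q) != length(experimental$q) ||
      any(abs(computed$q - experimental$q) > 1e-10)) {
    abort("computed and experimental curves must share one q grid")
  }
  sig <- if ("sigma" %in% names(experimental)) experimental$sigma else NULL
  if (is.null(sig)) abort("experimental curve lacks sigma")
  if (any(sig <= 0)) abort("sigma must be positive")
  w <- 1 / sig^2
  Ic <- computed$I
  Ie <- experimental$I
  if (fit_constant) {
    A <- rbind(c(sum(w * Ic^2), sum(w * Ic)),
               c(sum(w * Ic), sum(w)))
    b <- c(sum(w * Ic * Ie), sum(w * Ie))
    sol <- solve(A, b)
    cc <- sol[1]; const <- sol[2]
  } else {
    cc <- sum(w * Ie * Ic) / sum(w * Ic^2)
    const <- 0
  }
  resid <- (Ie - cc * Ic - const) / sig
  chi2 <- sum(resid^2)
  structure(
    list(c = cc, constant = const, chi2 = chi2,
         chi2_red = chi2 / length(Ie), n_points = length(Ie)),
    class = "saxs_fit"
  )
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("SAXS fit: c = %.6g, constant = %.6g, chi2 = %.6g, chi2_red = %.6g (N = %d)\n",
              x$c, x$constant, x$chi2, x$chi2_red, x$n_points))
  invisible(x)
}

#' Read and write 3-column SAXS curve files
#'
#' Whitespace- or comma-separated text tables of (q, I, sigma); a sigma
#' column is optional on computed curves. Lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return a scattering-curve tibble (`q`, `I` and `sigma` when present).
#' @export
read_saxs_curve <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("no data rows in curve file: ", path))
  parts <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 2)) {
    abort(paste0("malformed curve row (need >= 2 columns) at data line ",
                 which(ncols < 2)[1], " of ", path))
  }
  if (length(unique(pmin(ncols, 3))) != 1) {
    abort(paste0("inconsistent column count in curve file: ", path))
  }
  num <- lapply(parts, function(p) suppressWarnings(as.numeric(p[1:min(3, length(p))])))
  if (any(vapply(num, anyNA, logical(1)))) {
    abort(paste0("non-numeric value at data line ",
                 which(vapply(num, anyNA, logical(1)))[1], " of ", path))
  }
  m <- do.call(rbind, num)
  out <- tibble(q = m[, 1], I = m[, 2])
  if (ncol(m) >= 3) out$sigma <- m[, 3]
  if (is.unsorted(out$q, strictly = TRUE)) abort("q grid must be strictly increasing")
  if (!is.null(out$sigma) && any(out$sigma <= 0)) abort("sigma must be positive")
  out
}

#' @rdname read_saxs_curve
#' @param curve scattering-curve tibble.
#' @export
write_saxs_curve <- function(curve, path) {
  header <- "# q[1/A]  I(q)  sigma"
  cols <- c("q", "I", if ("sigma" %in% names(curve)) "sigma")
  lines <- do.call(sprintf, c(
    list(paste(rep("%.8g", length(cols)), collapse = "  ")),
    lapply(cols, function(cl) curve[[cl]])
  ))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Interpolate a computed curve onto an experimental q grid
#'
#' Linear interpolation in q; extrapolation outside the computed range is an
#' error.
#'
#' @param curve computed scattering-curve tibble.
#' @param q target grid.
#' @export
interpolate_curve <- function(curve, q) {
  if (min(q) < min(curve$q) - 1e-12 || max(q) > max(curve$q) + 1e-12) {
    abort("target q grid extends beyond the computed curve (extrapolation refused)")
  }
  tibble(q = q, I = approx(curve$q, curve$I, xout = q)$y)
}
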