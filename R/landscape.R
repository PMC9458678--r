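# Weighted ensemble observables: free-energy surfaces over collective
# variables, difference landscapes, weighted Rg statistics, Rg-threshold
# subensembles, and block-averaging error estimates.

#' Weighted free-energy surface over two collective variables
#'
#' Bins per-frame collective-variable values into a weighted 2-D histogram h
#' and converts populations to relative free energy
#' \eqn{F = -k_B T \ln(h / h_{max})}, so the most populated bin sits at
#' F = 0 and empty bins are masked (NA), never zero.
#'
#' @param cv1,cv2 per-frame collective-variable values (Angstrom).
#' @param weights frame weights (uniform when `NULL`); any positive rescaling
#'   leaves F unchanged.
#' @param bins bins per axis (scalar or length 2); the range is the observed
#'   CV range padded by 2%.
#' @param temperature temperature in K, used when `units = "kcal/mol"`.
#' @param units `"kT"` (default) or `"kcal/mol"`.
#' @return a `free_energy_surface` object: `F` matrix (bins1 x bins2,
#'   NA-masked), bin `edges1`/`edges2`, `units`, `temperature`.
#' @export
free_energy_surface <- function(cv1, cv2, weights = NULL, bins = 40,
                                temperature = 300, units = c("kT", "kcal/mol")) {
  units <- match.arg(units)
  if (length(cv1) != length(cv2)) abort("collective variables differ in length")
  if (is.null(weights)) weights <- rep(1, length(cv1))
  if (length(weights) != length(cv1)) abort("weights must align with the CV arrays")
  if (all(weights == 0)) abort("all-zero weights")
  bins <- rep(bins, length.out = 2)
  if (any(bins < 2)) abort("need at least 2 bins per axis")
  pad <- function(x) {
    r <- range(x)
    span <- diff(r)
    if (span == 0) span <- max(abs(r[1]), 1)
    c(r[1] - 0.02 * span, r[2] + 0.02 * span)
  }
  e1 <- seq(pad(cv1)[1], pad(cv1)[2], length.out = bins[1] + 1)
  e2 <- seq(pad(cv2)[1], pad(cv2)[2], length.out = bins[2] + 1)
  i1 <- findInterval(cv1, e1, rightmost.closed = TRUE)
  i2 <- findInterval(cv2, e2, rightmost.closed = TRUE)
  h <- matrix(0, bins[1], bins[2])
  for (k in seq_along(cv1)) h[i1[k], i2[k]] <- h[i1[k], i2[k]] + weights[k]
  if (max(h) <= 0) abort("empty histogram")
  kT <- if (units == "kT") 1 else 0.0019872041 * temperature
  F <- -kT * log(h / max(h))
  F[h == 0] <- NA_real_
  structure(
    list(F = F, edges1 = e1, edges2 = e2, units = units,
         temperature = temperature, weights = weights),
    class = "free_energy_surface"
  )
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("Free-energy surface: %d x %d bins, %d occupied, units %s\n",
              nrow(x$F), ncol(x$F), sum(!is.na(x$F)), x$units))
  invisible(x)
}

#' Difference between two free-energy landscapes
#'
#' Per-bin `reweighted - initial` free-energy difference on identical
#' binning; bins empty in either surface are masked. Negative values mark
#' regions up-weighted by the reweighting.
#'
#' @param reweighted,initial `free_energy_surface` objects on one binning.
#' @return matrix of free-energy differences (NA-masked).
#' @export
difference_landscape <- function(reweighted, initial) {
  if (!isTRUE(all.equal(reweighted$edges1, initial$edges1)) ||
      !isTRUE(all.equal(reweighted$edges2, initial$edges2))) {
    abort("free-energy surfaces have different binning")
  }
  reweighted$F - initial$F
}

#' Weighted radius-of-gyration statistics
#'
#' @param rg per-frame Rg values (Angstrom).
#' @param weights frame weights (uniform when `NULL`).
#' @param breaks histogram breaks or bin count passed to the distribution.
#' @return list: `histogram` tibble (`rg`, `density`), `mean`, `sd`
#'   (weighted population standard deviation).
#' @export
weighted_rg_stats <- function(rg, weights = NULL, breaks = 30) {
  if (is.null(weights)) weights <- rep(1, length(rg))
  if (length(weights) != length(rg)) abort("weights must align with rg")
  wn <- weights / sum(weights)
  mu <- sum(wn * rg)
  sdev <- sqrt(sum(wn * (rg - mu)^2))
  if (length(breaks) == 1) {
    breaks <- seq(min(rg), max(rg), length.out = breaks + 1)
    if (min(rg) == max(rg)) breaks <- c(min(rg) - 0.5, max(rg) + 0.5)
  }
  bin <- findInterval(rg, breaks, rightmost.closed = TRUE)
  dens <- vapply(seq_len(length(breaks) - 1),
                 function(b) sum(wn[bin == b]), numeric(1))
  widths <- diff(breaks)
  list(
    histogram = tibble(rg = (breaks[-1] + breaks[-length(breaks)]) / 2,
                       density = dens / widths),
    mean = mu, sd = sdev
  )
}

#' Split frames by an Rg threshold
#'
#' Partitions frame indices into compact (Rg <= threshold) and extended
#' (Rg > threshold) subensembles; boundary frames count as compact.
#'
#' @param rg per-frame Rg values.
#' @param threshold split value in Angstrom (default 30).
#' @return list with integer vectors `below` and `above`.
#' @export
split_by_rg <- function(rg, threshold = 30) {
  list(below = which(rg <= threshold), above = which(rg > threshold))
}

#' Block-averaging standard error for correlated series
#'
#' Blocks the series at doubling block sizes, computes the blocked standard
#' error of the mean at each size, and reports the plateau as the maximum
#' blocked SEM over block sizes that retain at least 8 blocks. For
#' uncorrelated data this approaches the naive SEM; positive autocorrelation
#' inflates the estimate towards the true error of the mean.
#'
#' @param series numeric vector, length >= 16.
#' @return the plateau standard-error estimate; attribute `"blocked"` holds
#'   the per-block-size tibble (`block_size`, `n_blocks`, `sem`).
#' @export
block_error <- function(series) {
  n <- length(series)
  if (n < 16) abort("series too short for block analysis (need >= 16)")
  sizes <- 2^(0:floor(log2(n / 8)))
  rows <- lapply(sizes, function(b) {
    nb <- floor(n / b)
    bm <- colMeans(matrix(series[seq_len(nb * b)], nrow = b))
    tibble(block_size = b, n_blocks = nb, sem = sd(bm) / sqrt(nb))
  })
  blocked <- bind_rows(rows)
  est <- max(blocked$sem)
  attr(est, "blocked") <- blocked
  est
}
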