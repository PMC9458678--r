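# Shared fixtures: small conformers built in code, random rigid-body
# transforms, and independent brute-force oracles.

toy_conformer <- function(coords, mass = 1, element = "BD",
                          resid = seq_len(nrow(coords))) {
  coords <- matrix(coords, ncol = 3)
  as_conformer(tibble::tibble(
    element = element, atom = "CA", resname = "ALA",
    resid = resid, chain = "A", mass = mass,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  ))
}

random_conformer <- function(n, seed = 1, spread = 20) {
  set.seed(seed)
  toy_conformer(matrix(runif(3 * n, -spread, spread), ncol = 3))
}

# random proper rotation + translation applied to a conformer
random_rigid_transform <- function(conf, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- runif(3, -50, 50)
  co <- as.matrix(conf[, c("x", "y", "z")]) %*% t(R)
  conf$x <- co[, 1] + t_vec[1]
  conf$y <- co[, 2] + t_vec[2]
  conf$z <- co[, 3] + t_vec[3]
  conf
}

# O(N^2) double-sum Debye oracle, written independently of debye_curve()
debye_oracle <- function(coords, q, f = NULL) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (is.null(f)) f <- matrix(1, length(q), n)
  vapply(seq_along(q), function(k) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        s <- if (q[k] * r == 0) 1 else sin(q[k] * r) / (q[k] * r)
        acc <- acc + f[k, i] * f[k, j] * s
      }
    }
    acc
  }, numeric(1))
}

# analytic Guinier-law curve
guinier_curve <- function(rg, i0 = 100, q = seq(0.002, 0.2, length.out = 120),
                          sigma_frac = NULL) {
  I <- i0 * exp(-q^2 * rg^2 / 3)
  out <- tibble::tibble(q = q, I = I)
  if (!is.null(sigma_frac)) out$sigma <- sigma_frac * I
  out
}

# simple analytic two-profile family for inference toys
analytic_profiles <- function(q = seq(0.01, 0.3, length.out = 100),
                              decay = c(300, 1200)) {
  lapply(decay, function(a) tibble::tibble(q = q, I = exp(-q^2 * a)))
}

expect_on_simplex <- function(w, tol = 1e-8) {
  expect_true(all(w >= -tol))
  expect_lt(abs(sum(w) - 1), tol)
}
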