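# 1-D grid-search oracle for the theta -> 0 limit: least-squares weights on
# the K = 2 simplex, independent of the quasi-Newton path.
grid_search_weights <- function(profiles, curve, n_grid = 20001) {
  w_grid <- seq(0, 1, length.out = n_grid)
  chi2 <- vapply(w_grid, function(w) {
    chi2_of_weights(c(w, 1 - w), profiles, curve)
  }, numeric(1))
  w_grid[which.min(chi2)]
}

test_that("KL divergence matches analytic values and Gibbs' inequality", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  set.seed(11)
  for (i in 1:20) {
    w <- runif(5); w <- w / sum(w)
    w0 <- runif(5); w0 <- w0 / sum(w0)
    expect_gte(kl_divergence(w, w0), 0)
  }
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "infinite divergence")
})

test_that("negative log-posterior decomposes into theta * S_KL + chi2 / 2", {
  q <- seq(0.01, 0.3, length.out = 50)
  profs <- c(analytic_profiles(q), analytic_profiles(q, decay = 700))
  mix <- weighted_average_profile(c(0.2, 0.3, 0.5), profs)
  set.seed(12)
  curve <- tibble::tibble(q = q, I = mix$I + rnorm(50, 0, 0.01), sigma = 0.01)
  w0 <- rep(1 / 3, 3)
  w <- c(0.5, 0.25, 0.25)
  theta <- 7.5
  # independent term-by-term evaluation
  expected <- theta * sum(w * log(w / w0)) +
    chi2_of_weights(w, profs, curve) / 2
  expect_equal(neg_log_posterior(w, theta, profs, curve, w0), expected,
               tolerance = 1e-12)
  expect_equal(neg_log_posterior(w0, 0, profs, curve, w0),
               chi2_of_weights(w0, profs, curve) / 2, tolerance = 1e-12)
})

test_that("analytic gradient of L matches finite differences", {
  q <- seq(0.01, 0.3, length.out = 40)
  profs <- c(analytic_profiles(q), analytic_profiles(q, decay = 700))
  mix <- weighted_average_profile(c(0.4, 0.4, 0.2), profs)
  set.seed(13)
  curve <- tibble::tibble(q = q, I = mix$I + rnorm(40, 0, 0.02), sigma = 0.02)
  st <- saxsens:::chi2_stats(profs, curve)
  w0 <- rep(1 / 3, 3)
  theta <- 3
  cc <- 1.1
  obj <- function(g) {
    w <- exp(g - max(g)); w <- w / sum(w)
    bw <- as.vector(st$B %*% w)
    theta * sum(w * log(w / w0)) +
      (st$C - 2 * cc * sum(st$A * w) + cc^2 * sum(w * bw)) / 2
  }
  grad_analytic <- function(g) {
    w <- exp(g - max(g)); w <- w / sum(w)
    bw <- as.vector(st$B %*% w)
    v <- theta * (log(w / w0) + 1) + cc^2 * bw - cc * st$A
    w * (v - sum(w * v))
  }
  g <- c(0.3, -0.2, 0.1)
  fd <- vapply(1:3, function(i) {
    h <- 1e-6
    gp <- g; gp[i] <- gp[i] + h
    gm <- g; gm[i] <- gm[i] - h
    (obj(gp) - obj(gm)) / (2 * h)
  }, numeric(1))
  expect_equal(grad_analytic(g), fd, tolerance = 1e-6)
})

test_that("huge theta pins the solution to the reference weights", {
  q <- seq(0.01, 0.3, length.out = 60)
  profs <- analytic_profiles(q)
  mix <- weighted_average_profile(c(0.8, 0.2), profs)
  set.seed(14)
  curve <- tibble::tibble(q = q, I = mix$I + rnorm(60, 0, 0.01), sigma = 0.01)
  fit <- optimize_weights(1e12, c(0.5, 0.5), profs, curve)
  expect_lt(max(abs(fit$weights - 0.5)), 1e-6)
  expect_lt(fit$s_kl, 1e-10)
})

test_that("theta -> 0 reproduces the grid-search least-squares solution", {
  for (s in 1:20) {
    set.seed(200 + s)
    q <- seq(0.01, 0.3, length.out = 60)
    # two experimentally distinguishable states, noiseless observation
    profs <- analytic_profiles(q, decay = c(runif(1, 100, 500),
                                            runif(1, 900, 2000)))
    w_true <- runif(1, 0.15, 0.85)
    mix <- weighted_average_profile(c(w_true, 1 - w_true), profs)
    curve <- dplyr::mutate(mix, sigma = 0.005)
    fit <- optimize_weights(1e-6, c(0.5, 0.5), profs, curve)
    oracle <- grid_search_weights(profs, curve)
    expect_lt(abs(fit$weights[1] - oracle), 1e-3)
    expect_lt(abs(fit$weights[1] - w_true), 1e-3)
  }
})

test_that("the regularization path is monotone in theta", {
  q <- seq(0.01, 0.3, length.out = 60)
  profs <- c(analytic_profiles(q), analytic_profiles(q, decay = 700))
  mix <- weighted_average_profile(c(0.6, 0.1, 0.3), profs)
  set.seed(15)
  curve <- tibble::tibble(q = q, I = mix$I + rnorm(60, 0, 0.01), sigma = 0.01)
  lc <- theta_scan(profs, curve)
  # S_KL non-increasing, chi2 non-decreasing as theta grows
  expect_true(all(diff(lc$curve$s_kl) <= 1e-8))
  expect_true(all(diff(lc$curve$chi2_red) >= -1e-8))
})

test_that("theta scan handles a single-point grid", {
  q <- seq(0.01, 0.3, length.out = 40)
  profs <- analytic_profiles(q)
  mix <- weighted_average_profile(c(0.5, 0.5), profs)
  curve <- dplyr::mutate(mix, sigma = 0.02)
  lc <- theta_scan(profs, curve, theta_grid = 100)
  expect_equal(nrow(lc$curve), 1)
  expect_equal(lc$selected_theta, 100)
})

test_that("a constructed sharp corner is selected as the L-curve elbow", {
  # geometry: flat arm, corner, steep arm in (S_KL, chi2_red) log-log space
  s_kl <- c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1)
  chi2 <- c(1000, 998, 995, 990, 10, 9.8, 9.5)
  elbow <- select_elbow(s_kl, chi2)
  expect_true(elbow %in% c(4, 5))  # the corner pair
})

test_that("significant conformers follow the mean + population-sd rule", {
  expect_length(significant_conformers(rep(0.25, 4)), 0)
  expect_equal(significant_conformers(c(0.7, 0.1, 0.1, 0.1)), 1L)
  w <- c(0.96, rep(0.04 / 49, 49))
  expect_equal(significant_conformers(w), 1L)
})

test_that("optimized weights stay on the simplex and S_KL is 0 iff w = w0", {
  q <- seq(0.01, 0.3, length.out = 40)
  profs <- c(analytic_profiles(q), analytic_profiles(q, decay = 700))
  mix <- weighted_average_profile(c(0.2, 0.5, 0.3), profs)
  set.seed(16)
  curve <- tibble::tibble(q = q, I = mix$I + rnorm(40, 0, 0.01), sigma = 0.01)
  fit <- optimize_weights(10, rep(1 / 3, 3), profs, curve)
  expect_on_simplex(fit$weights)
  expect_gt(fit$s_kl, 0)
  expect_gte(kl_divergence(fit$weights, fit$w0), 0)
})
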