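test_that("Debye curve matches analytic one- and two-scatterer forms", {
  q <- seq(0, 0.5, length.out = 21)
  one <- debye_curve(toy_conformer(c(0, 0, 0)), q)
  expect_equal(one$I, rep(1, 21))
  two <- debye_curve(toy_conformer(rbind(c(0, 0, 0), c(10, 0, 0))), q)
  expected <- ifelse(q == 0, 4, 2 * (1 + sin(10 * q) / (10 * q)))
  expect_equal(two$I, expected, tolerance = 1e-12)
  expect_equal(two$I[1], 4)  # I(0) = (sum f)^2
})

test_that("Debye curve agrees with the O(N^2) double-sum oracle to 1e-10", {
  conf <- random_conformer(50, seed = 42)
  q <- seq(0, 0.4, length.out = 25)
  got <- debye_curve(conf, q)$I
  want <- debye_oracle(as.matrix(conf[, c("x", "y", "z")]), q)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("Debye output is rigid-body invariant and strictly positive", {
  conf <- random_conformer(30, seed = 8)
  q <- seq(0, 0.5, length.out = 30)
  base <- debye_curve(conf, q)$I
  moved <- debye_curve(random_rigid_transform(conf, seed = 88), q)$I
  expect_equal(moved, base, tolerance = 1e-9)
  expect_true(all(base > 0))
  expect_error(debye_curve(conf, c(-0.1, 0.1)), "negative q")
})

test_that("atomic form factors reduce to electron counts at q = 0", {
  conf <- toy_conformer(rbind(c(0, 0, 0), c(5, 0, 0)), element = c("C", "ZN"))
  I0 <- debye_curve(conf, 0, form_factor_model = "atomic")$I
  f0 <- 6 + 30
  expect_equal(I0, f0^2, tolerance = 0.01 * f0^2)  # Cromer-Mann f(0) ~ Z
})

test_that("weighted average profile is a pointwise convex combination", {
  q <- seq(0.01, 0.3, length.out = 10)
  p1 <- tibble::tibble(q = q, I = rep(1, 10))
  p2 <- tibble::tibble(q = q, I = rep(2, 10))
  expect_equal(weighted_average_profile(1, list(p1))$I, p1$I)
  expect_equal(weighted_average_profile(c(0.3, 0.7), list(p1, p1))$I, p1$I)
  expect_equal(weighted_average_profile(c(0.25, 0.75), list(p1, p2))$I,
               rep(1.75, 10))
  expect_error(weighted_average_profile(c(0.5, 0.6), list(p1, p2)), "sum to 1")
  p3 <- tibble::tibble(q = q + 0.001, I = rep(1, 10))
  expect_error(weighted_average_profile(c(0.5, 0.5), list(p1, p3)), "grid")
})

test_that("fit_to_experiment recovers scale and offset", {
  q <- seq(0.01, 0.3, length.out = 40)
  comp <- tibble::tibble(q = q, I = exp(-q^2 * 300))
  exp_same <- dplyr::mutate(comp, sigma = 1)
  f0 <- fit_to_experiment(comp, exp_same)
  expect_equal(f0$c, 1)
  expect_equal(f0$chi2, 0, tolerance = 1e-20)

  exp2 <- tibble::tibble(q = q, I = 2 * comp$I, sigma = 1)
  f2 <- fit_to_experiment(comp, exp2)
  expect_equal(f2$c, 2)
  expect_equal(f2$chi2, 0, tolerance = 1e-20)

  exp3 <- tibble::tibble(q = q, I = 3 * comp$I + 0.5, sigma = 1)
  f3 <- fit_to_experiment(comp, exp3, fit_constant = TRUE)
  expect_equal(f3$c, 3, tolerance = 1e-9)
  expect_equal(f3$constant, 0.5, tolerance = 1e-9)
})

test_that("closed-form scale matches the normal-equation oracle on a toy", {
  comp <- tibble::tibble(q = 1:3, I = c(1, 2, 3))
  expc <- tibble::tibble(q = 1:3, I = c(2.1, 3.9, 6.0), sigma = 1)
  f <- fit_to_experiment(comp, expc)
  # independent weighted least squares via lm
  oracle <- unname(coef(lm(expc$I ~ 0 + comp$I)))
  expect_equal(f$c, oracle, tolerance = 1e-12)
  expect_equal(f$chi2_red, f$chi2 / 3)
})

test_that("chi2 is invariant under joint rescaling of data, sigma and model", {
  q <- seq(0.01, 0.3, length.out = 30)
  set.seed(4)
  comp <- tibble::tibble(q = q, I = exp(-q^2 * 400))
  expc <- tibble::tibble(q = q, I = comp$I * 2 + rnorm(30, 0, 0.01), sigma = 0.01)
  f1 <- fit_to_experiment(comp, expc)
  scaled <- tibble::tibble(q = q, I = 10 * expc$I, sigma = 10 * expc$sigma)
  f2 <- fit_to_experiment(comp, scaled)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-9)
  expect_equal(f2$c, 10 * f1$c, tolerance = 1e-9)
})

test_that("curve files round-trip and malformed files are named errors", {
  q <- seq(0.01, 0.2, length.out = 15)
  curve <- tibble::tibble(q = q, I = exp(-q^2 * 200), sigma = 0.01 * exp(-q^2 * 200))
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_curve(curve, path)
  back <- read_saxs_curve(path)
  expect_equal(back$q, curve$q, tolerance = 1e-7)
  expect_equal(back$I, curve$I, tolerance = 1e-7)
  expect_equal(back$sigma, curve$sigma, tolerance = 1e-7)

  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# header", "0.01 1.0 0.1", "0.02"), bad)
  expect_error(read_saxs_curve(bad), "line")
  bad2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 1.0 0.1", "0.02 x 0.1"), bad2)
  expect_error(read_saxs_curve(bad2), "non-numeric")
})

test_that("interpolation refuses extrapolation", {
  curve <- tibble::tibble(q = seq(0.05, 0.2, 0.01), I = 1)
  expect_equal(interpolate_curve(curve, c(0.06, 0.15))$I, c(1, 1))
  expect_error(interpolate_curve(curve, c(0.01, 0.1)), "extrapolation")
})
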