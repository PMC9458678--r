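test_that("PDB round-trip preserves models, coordinates and atom order", {
  toy <- generate_toy_ensemble(3, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(toy$ensemble, path)
  ens <- read_coordinates(path, format = "pdb")
  expect_equal(n_frames(ens), 3)
  expect_equal(nrow(ens), nrow(toy$ensemble))
  expect_equal(ens$resid, toy$ensemble$resid)
  expect_equal(ens$x, toy$ensemble$x, tolerance = 1e-3)  # fixed-width %.3f
  expect_equal(ens$y, toy$ensemble$y, tolerance = 1e-3)
})

test_that("single-model single-atom PDB reads as one conformer, one atom", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A 699       1.000   2.000   3.000  1.00  0.00           C",
    "END"
  ), path)
  ens <- read_coordinates(path)
  expect_equal(n_frames(ens), 1)
  expect_equal(nrow(ens), 1)
  expect_equal(c(ens$x, ens$y, ens$z), c(1, 2, 3))
})

test_that("XYZ reader parses frames and flags malformed records by line", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "2", "frame 1", "C 0 0 0", "C 1 0 0",
    "2", "frame 2", "C 0 0 1", "C 1 0 1"
  ), path)
  ens <- read_coordinates(path)
  expect_equal(n_frames(ens), 2)
  expect_equal(ens$z[ens$frame == 2], c(1, 1))

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "frame", "C 0 0 0", "C 1 0"), bad)
  expect_error(read_coordinates(bad), "line")
  expect_error(read_coordinates(withr::local_tempfile(fileext = ".xyz")),
               "not found")
})

test_that("center of mass follows hand-computed mass weighting", {
  expect_equal(unname(center_of_mass(toy_conformer(c(1, 2, 3)))), c(1, 2, 3))
  two <- toy_conformer(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unname(center_of_mass(two)), c(1, 0, 0))
  uneq <- toy_conformer(rbind(c(0, 0, 0), c(4, 0, 0)), mass = c(1, 3))
  expect_equal(unname(center_of_mass(uneq)), c(3, 0, 0))
  expect_error(center_of_mass(two, c(50, 60)), "empty")
})

test_that("domain distances are COM distances", {
  conf <- toy_conformer(rbind(c(0, 0, 0), c(3, 0, 0)), resid = c(1, 10))
  d1 <- domain_def("a", 1, 5)
  d2 <- domain_def("b", 6, 12)
  expect_equal(domain_distance(conf, d1, d2), 3)
  expect_equal(domain_distance(conf, d1, d1), 0)
})

test_that("radius of gyration and Dmax match analytic cases", {
  expect_equal(radius_of_gyration(toy_conformer(c(5, 5, 5))), 0)
  pair <- toy_conformer(rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(radius_of_gyration(pair), 3)  # d/2 for equal masses
  expect_equal(max_dimension(pair), 6)
  cube <- toy_conformer(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(max_dimension(cube), sqrt(3))
  expect_error(max_dimension(toy_conformer(c(0, 0, 0))), "2 atoms")
})

test_that("Rg never exceeds Dmax; equals Dmax/2 for two equal points", {
  for (s in 1:5) {
    conf <- random_conformer(30, seed = s)
    expect_lt(radius_of_gyration(conf), max_dimension(conf))
  }
  pair <- toy_conformer(rbind(c(0, 0, 0), c(0, 0, 9)))
  expect_equal(radius_of_gyration(pair), max_dimension(pair) / 2)
})

test_that("structural metrics are rigid-body invariant", {
  conf <- random_conformer(40, seed = 7)
  d1 <- domain_def("a", 1, 20)
  d2 <- domain_def("b", 21, 40)
  ens0 <- conf; ens0$frame <- 1L
  f0 <- ca_distance_features(ens0, rbind(d1, d2))
  for (s in 1:5) {
    tr <- random_rigid_transform(conf, seed = 100 + s)
    expect_equal(radius_of_gyration(tr), radius_of_gyration(conf), tolerance = 1e-9)
    expect_equal(max_dimension(tr), max_dimension(conf), tolerance = 1e-9)
    expect_equal(domain_distance(tr, d1, d2), domain_distance(conf, d1, d2),
                 tolerance = 1e-9)
    ens_t <- tr; ens_t$frame <- 1L
    expect_equal(as.vector(ca_distance_features(ens_t, rbind(d1, d2))),
                 as.vector(f0), tolerance = 1e-9)
  }
})

test_that("C-alpha distance features follow the canonical pair order", {
  conf <- toy_conformer(rbind(c(0, 0, 0), c(3, 0, 0), c(7, 0, 0)))
  conf$frame <- 1L
  f <- ca_distance_features(conf, domain_def("a", 1, 3))
  expect_equal(ncol(f), 3)  # n(n-1)/2 for n = 3
  expect_equal(as.vector(f), c(3, 7, 4))
})

test_that("superpose_and_graft is identity for donor == target and inverts rotations", {
  conf <- random_conformer(30, seed = 3)
  conf$atom <- rep(c("N", "CA", "C"), length.out = 30)
  conf$resid <- rep(1:10, each = 3)
  out <- superpose_and_graft(conf, conf, c(1, 10), c(6, 10))
  expect_equal(out$x, conf$x, tolerance = 1e-9)
  expect_equal(attr(out, "superpose_rmsd"), 0, tolerance = 1e-9)

  rot <- conf
  co <- as.matrix(conf[, c("x", "y", "z")])
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  co_r <- co %*% t(Rz)
  rot$x <- co_r[, 1]; rot$y <- co_r[, 2]; rot$z <- co_r[, 3]
  out2 <- superpose_and_graft(conf, rot, c(1, 10), c(6, 10))
  expect_lt(attr(out2, "superpose_rmsd"), 1e-6)
  expect_equal(out2$x, conf$x, tolerance = 1e-6)
})

test_that("grafting composes target and transformed donor fragments", {
  target <- random_conformer(30, seed = 5)
  target$atom <- rep(c("N", "CA", "C"), length.out = 30)
  target$resid <- rep(1:10, each = 3)
  donor0 <- target
  donor0$x[donor0$resid > 7] <- donor0$x[donor0$resid > 7] + 5  # donor-specific tail
  donor <- random_rigid_transform(donor0, seed = 9)
  out <- superpose_and_graft(target, donor, align_range = c(5, 7),
                             replace_range = c(8, 10))
  expect_equal(out$resid, target$resid)
  expect_equal(out$x[out$resid <= 7], target$x[target$resid <= 7], tolerance = 1e-9)
  # grafted tail carries the donor offset, mapped into the target frame
  expect_equal(out$x[out$resid > 7], target$x[target$resid > 7] + 5, tolerance = 1e-6)
})

test_that("superposition matches the bio3d least-squares fit", {
  conf <- random_conformer(24, seed = 13)
  conf$atom <- rep(c("N", "CA", "C"), length.out = 24)
  conf$resid <- rep(1:8, each = 3)
  donor <- random_rigid_transform(conf, seed = 14)
  out <- superpose_and_graft(conf, donor, c(1, 8), c(1, 8))
  fixed <- as.numeric(t(as.matrix(conf[, c("x", "y", "z")])))
  mobile <- as.numeric(t(as.matrix(donor[, c("x", "y", "z")])))
  fitted <- bio3d::fit.xyz(fixed, mobile, 1:24, 1:24)
  expect_equal(out$x, fitted[seq(1, 72, 3)], tolerance = 1e-6)
})

test_that("domain YAML round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(domains = list(
    list(name = "RING1", start = 699, end = 751),
    list(name = "IBR", start = 796, end = 841)
  )), path)
  doms <- read_domains_yaml(path)
  expect_equal(doms$name, c("RING1", "IBR"))
  expect_equal(doms$start, c(699L, 796L))
  expect_error(domain_def("x", 10, 5), "start")
})

test_that("ensemble invariants are enforced", {
  expect_error(as_conformer(tibble::tibble(element = "C", resid = 1,
                                           x = NaN, y = 0, z = 0)), "finite")
  expect_error(as_ensemble(list()), "empty")
  a <- toy_conformer(c(0, 0, 0)); b <- toy_conformer(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(as_ensemble(list(a, b)), "same atom count")
})
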