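make_blobs <- function(centers, n_each, sd = 0.05, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_each * ncol(centers), 0, sd), n_each) +
      matrix(centers[i, ], n_each, ncol(centers), byrow = TRUE)
  }))
  truth <- rep(seq_len(nrow(centers)), each = n_each)
  list(X = X, truth = truth)
}

test_that("well-separated blobs are recovered exactly", {
  b <- make_blobs(rbind(c(0, 0), c(10, 10)), n_each = 50, sd = 0.1, seed = 2)
  labels <- hdbscan_labels(b$X, min_cluster_size = 5)
  expect_equal(sort(unique(labels)), c(1L, 2L))
  # one-to-one mapping between found labels and ground truth
  expect_equal(length(unique(paste(labels, b$truth))), 2)
})

test_that("fewer frames than the minimum cluster size are all noise", {
  X <- matrix(rnorm(8), 4, 2)
  expect_equal(hdbscan_labels(X, min_cluster_size = 5), rep(-1L, 4))
})

test_that("duplicating points of one blob does not change the cluster count", {
  b <- make_blobs(rbind(c(0, 0), c(10, 10)), n_each = 40, sd = 0.1, seed = 3)
  labels1 <- hdbscan_labels(b$X, min_cluster_size = 5)
  dup <- rbind(b$X, b$X[b$truth == 1, ])
  labels2 <- hdbscan_labels(dup, min_cluster_size = 5)
  expect_equal(length(unique(labels1[labels1 > 0])),
               length(unique(labels2[labels2 > 0])))
})

test_that("degenerate all-identical features form one cluster with no noise", {
  X <- matrix(1, 20, 3)
  labels <- hdbscan_labels(X, min_cluster_size = 5)
  expect_equal(labels, rep(1L, 20))
})

test_that("noise and cluster sizes account for every frame", {
  b <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), n_each = 30, sd = 0.2, seed = 4)
  X <- rbind(b$X, matrix(runif(10, -20, 20), 5, 2))  # scattered outliers
  assign_tbl <- cluster_conformers(X, min_cluster_size = 5)
  sizes <- table(assign_tbl$label)
  expect_equal(sum(sizes), nrow(X))
  expect_true(all(sizes[names(sizes) != "-1"] >= 5))
  # each cluster has exactly one representative, drawn from its members
  for (cl in unique(assign_tbl$label[assign_tbl$label > 0])) {
    reps <- assign_tbl$frame[assign_tbl$representative & assign_tbl$label == cl]
    expect_length(reps, 1)
  }
})

test_that("representative member minimises the summed pairwise RMSD score", {
  expect_equal(representative_member(matrix(5, 1, 2)), 1L)
  f <- matrix(c(0, 1, 10), ncol = 1)
  # pairwise |differences|: scores (11, 10, 19) -> middle member
  expect_equal(representative_member(f), 2L)
  sym <- matrix(c(0, 4), ncol = 1)
  expect_equal(representative_member(sym), 1L)  # tie broken to lowest index
})

test_that("representative member equals exhaustive-search argmin", {
  brute <- function(F) {
    R <- matrix(0, nrow(F), nrow(F))
    for (i in seq_len(nrow(F))) {
      for (j in seq_len(nrow(F))) {
        R[i, j] <- sqrt(mean((F[i, ] - F[j, ])^2))
      }
    }
    which.min(colSums(R))
  }
  for (s in 1:5) {
    set.seed(40 + s)
    F <- matrix(rnorm(sample(20:200, 1) * 4), ncol = 4)
    expect_equal(representative_member(F), brute(F))
  }
})

test_that("profile clustering separates distinguishable groups and collapses duplicates", {
  q <- seq(0.01, 0.3, length.out = 50)
  sigma <- rep(0.01, 50)
  base1 <- exp(-q^2 * 300)
  base2 <- exp(-q^2 * 1500)
  mkprof <- function(I) tibble::tibble(q = q, I = I)
  same <- replicate(4, mkprof(base1), simplify = FALSE)
  bs1 <- cluster_profiles(same, sigma)
  expect_length(bs1$members, 1)

  groups <- c(replicate(3, mkprof(base1), simplify = FALSE),
              replicate(3, mkprof(base2), simplify = FALSE))
  bs2 <- cluster_profiles(groups, sigma)
  expect_length(bs2$members, 2)
  expect_equal(unname(bs2$labels[1:3]), rep(bs2$labels[[1]], 3))
  expect_equal(unname(bs2$labels[4:6]), rep(bs2$labels[[4]], 3))

  bs3 <- cluster_profiles(groups, sigma, distance_threshold = 1e12)
  expect_length(bs3$members, 1)
  expect_error(cluster_profiles(groups[1], sigma), "at least 2")
})

test_that("profile clustering partition is invariant under reordering", {
  q <- seq(0.01, 0.3, length.out = 40)
  sigma <- rep(0.02, 40)
  set.seed(6)
  profs <- lapply(runif(8, 200, 2000),
                  function(a) tibble::tibble(q = q, I = exp(-q^2 * a)))
  bs <- cluster_profiles(profs, sigma)
  perm <- sample(8)
  bs_p <- cluster_profiles(profs[perm], sigma)
  # same partition up to label names
  part1 <- split(seq_len(8), bs$labels)
  part2 <- split(perm, bs_p$labels[order(seq_len(8))])
  part2 <- split(perm[order(perm)], bs_p$labels[match(seq_len(8), perm)])
  norm <- function(p) unname(lapply(p[order(vapply(p, min, 1))], sort))
  expect_equal(norm(part1), norm(part2))
})
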