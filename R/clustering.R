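#' Structural clustering of conformers on distance features
#'
#' First step of the basis-set selection protocol: density-based hierarchical
#' clustering ([hdbscan_labels()]) of frames on their pairwise C-alpha
#' distance features (Euclidean metric). Frames in low-density regions are
#' labelled noise (-1) and excluded downstream; each cluster gets a
#' representative frame by [representative_member()].
#'
#' @param features frames x features matrix (e.g. [ca_distance_features()]).
#' @param min_cluster_size minimum cluster size (protocol default 5).
#' @return tibble with one row per frame: `frame`, `label` (-1 = noise),
#'   `representative` (logical).
#' @export
cluster_conformers <- function(features, min_cluster_size = 5) {
  features <- as.matrix(features)
  labels <- hdbscan_labels(features, min_cluster_size = min_cluster_size)
  out <- tibble(frame = seq_len(nrow(features)), label = labels,
                representative = FALSE)
  for (cl in sort(unique(labels[labels > 0]))) {
    members <- which(labels == cl)
    rep_i <- members[representative_member(features[members, , drop = FALSE])]
    out$representative[rep_i] <- TRUE
  }
  out
}

#' Representative (centroid) member of a cluster
#'
#' Scores every member by the sum over the pairwise RMSD matrix of its
#' feature vectors, \eqn{\mathrm{score}_j = \sum_i R_{ij}}, and returns the
#' member with the lowest score (ties broken to the lowest index).
#'
#' @param cluster_features members x features matrix (or list of vectors).
#' @return index of the representative member within the cluster.
#' @export
representative_member <- function(cluster_features) {
  if (is.list(cluster_features) && !is.matrix(cluster_features)) {
    cluster_features <- do.call(rbind, cluster_features)
  }
  cluster_features <- as.matrix(cluster_features)
  m <- nrow(cluster_features)
  if (m == 0) abort("empty cluster")
  if (m == 1) return(1L)
  R <- as.matrix(dist(cluster_features)) / sqrt(ncol(cluster_features))
  unname(which.min(colSums(R)))
}

#' Scattering-profile clustering into a basis set
#'
#' Second step of the basis-set protocol: representative conformer profiles
#' are compared with the error-weighted pairwise dissimilarity
#' \deqn{\chi^2_{(i,j)} = \frac{1}{N_q}\sum_q \left(\frac{I_i(q) - I_j(q)}
#'   {\sigma_{exp}(q)}\right)^2} (per-point normalised; profiles first scaled
#' to I = 1 at the lowest q so the comparison is shape-based), agglomerated
#' with Ward's linkage and cut at a flat distance threshold. Per cluster the
#' profile closest to the cluster mean profile becomes the basis-set member.
#'
#' @param profiles list of scattering-curve tibbles on one shared q grid.
#' @param sigma experimental errors on that grid.
#' @param distance_threshold tree cut height (protocol default 0.15).
#' @param normalize scale profiles to unit intensity at the first grid point
#'   before comparison.
#' @return a `basis_set` object: `members` (indices into `profiles`),
#'   `labels` (cluster id per profile), `profiles` (member curves), `sigma`.
#' @export
cluster_profiles <- function(profiles, sigma, distance_threshold = 0.15,
                             normalize = TRUE) {
  np <- length(profiles)
  if (np < 2) abort("need at least 2 profiles to cluster")
  q0 <- profiles[[1]]$q
  Imat <- vapply(profiles, function(p) {
    if (length(p$q) != length(q0) || any(abs(p$q - q0) > 1e-10)) {
      abort("profiles must share one q grid")
    }
    p$I
  }, numeric(length(q0)))
  if (length(sigma) != length(q0)) abort("sigma must match the q grid")
  if (normalize) {
    # shape comparison: each profile scaled to unit intensity at the lowest
    # q, sigma rescaled by the profiles' common forward intensity so the
    # error stays commensurate with the normalised profiles
    sigma <- sigma / mean(Imat[1, ])
    Imat <- sweep(Imat, 2, Imat[1, ], `/`)
  }
  nq <- length(q0)
  sc <- Imat / sigma
  g <- crossprod(sc)
  chi2 <- (outer(diag(g), diag(g), `+`) - 2 * g) / nq
  chi2[chi2 < 0] <- 0
  tree <- hclust(stats::as.dist(chi2), method = "ward.D")
  labels <- cutree(tree, h = distance_threshold)
  members <- vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 1) return(idx)
    mean_prof <- rowMeans(Imat[, idx, drop = FALSE])
    dd <- colSums(((Imat[, idx, drop = FALSE] - mean_prof) / sigma)^2)
    idx[which.min(dd)]
  }, integer(1))
  structure(
    list(members = members, labels = labels,
         profiles = profiles[members], q = q0, sigma = sigma,
         distance_threshold = distance_threshold),
    class = "basis_set"
  )
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("Basis set: K = %d members from %d profiles (cut at %.3g)\n",
              length(x$members), length(x$labels), x$distance_threshold))
  invisible(x)
}
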