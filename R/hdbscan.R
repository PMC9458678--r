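# Density-based hierarchical clustering (the HDBSCAN* algorithm):
# mutual-reachability distances, a minimum spanning tree, the condensed
# cluster tree at a minimum cluster size, and excess-of-mass cluster
# selection. Dense-matrix implementation suitable for the ensemble sizes
# this package clusters (hundreds to a few thousand frames).

#' Density-based clustering of feature vectors (HDBSCAN*)
#'
#' @param X numeric matrix, observations in rows.
#' @param min_cluster_size smallest cluster size; smaller density peaks are
#'   treated as noise.
#' @param min_samples smoothing parameter for the core distance (the k-th
#'   nearest neighbour, self included); defaults to `min_cluster_size`.
#' @return integer labels, one per row: consecutive cluster ids starting at
#'   1, or -1 for noise.
#' @export
hdbscan_labels <- function(X, min_cluster_size = 5, min_samples = min_cluster_size) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (min_cluster_size < 2) abort("min_cluster_size must be >= 2")
  if (n < min_cluster_size) return(rep(-1L, n))
  D <- as.matrix(dist(X))
  if (max(D) < 1e-12) return(rep(1L, n))  # degenerate: one zero-diameter cluster

  k <- min(min_samples, n)
  core <- apply(D, 1, function(row) sort(row, partial = k)[k])
  M <- pmax(D, outer(core, core, pmax))

  mst <- prim_mst(M)
  mst <- mst[order(mst[, 3]), , drop = FALSE]

  tree <- single_linkage_tree(mst, n)
  cond <- condense_tree(tree, n, min_cluster_size)
  if (is.null(cond)) return(rep(-1L, n))
  select_and_label(cond, n)
}

# Prim's algorithm on a dense symmetric weight matrix; returns an
# (n-1) x 3 matrix of edges (i, j, weight).
prim_mst <- function(M) {
  n <- nrow(M)
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n)
  from <- rep(0L, n)
  in_tree[1] <- TRUE
  best_upd <- M[1, ]
  upd <- best_upd < best
  best[upd] <- best_upd[upd]
  from[upd] <- 1L
  best[1] <- Inf
  edges <- matrix(0, n - 1, 3)
  for (e in seq_len(n - 1)) {
    v <- which.min(replace(best, in_tree, Inf))
    edges[e, ] <- c(from[v], v, best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & M[v, ] < best
    best[upd] <- M[v, upd]
    from[upd] <- v
  }
  edges
}

# Union-find agglomeration of sorted MST edges into a binary merge tree.
# Node ids: 1..n leaves, n+1..2n-1 internal. Returns per-internal-node
# children ids, merge distance and subtree size.
single_linkage_tree <- function(edges, n) {
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  size <- c(rep(1L, n), rep(0L, n - 1L))
  child_l <- child_r <- integer(n - 1L)
  dist_m <- numeric(n - 1L)
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    nxt <- nxt + 1L
    child_l[nxt - n] <- a; child_r[nxt - n] <- b
    dist_m[nxt - n] <- edges[e, 3]
    size[nxt] <- size[a] + size[b]
    parent[a] <- nxt; parent[b] <- nxt
  }
  list(child_l = child_l, child_r = child_r, dist = dist_m, size = size, n = n)
}

subtree_leaves <- function(tree, node) {
  n <- tree$n
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, tree$child_l[v - n], tree$child_r[v - n])
  }
  out
}

# Condensed tree: records (parent cluster, child, lambda, size), where child
# is a point (<= n) or a new condensed cluster id (> n marker stored
# negatively as cluster index). Represented as a data frame with a flag.
condense_tree <- function(tree, n, mcs) {
  root <- 2L * n - 1L
  pos <- tree$dist[tree$dist > 0]
  d_floor <- if (length(pos) > 0) min(pos) * 1e-3 else NA_real_
  if (is.na(d_floor)) return(NULL)  # fully degenerate; handled by caller
  lam <- function(d) 1 / pmax(d, d_floor)

  par_v <- child_v <- integer(0)
  lambda_v <- numeric(0)
  size_v <- integer(0)
  is_cluster <- logical(0)
  n_clusters <- 1L
  add <- function(p, ch, l, s, cl) {
    par_v <<- c(par_v, p); child_v <<- c(child_v, ch)
    lambda_v <<- c(lambda_v, l); size_v <<- c(size_v, s)
    is_cluster <<- c(is_cluster, cl)
  }
  # stack of (binary node, condensed cluster id)
  stack <- list(c(root, 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    node <- top[1]; cid <- top[2]
    if (node <= n) next
    l <- tree$child_l[node - n]; r <- tree$child_r[node - n]
    lv <- lam(tree$dist[node - n])
    sl <- tree$size[l]; sr <- tree$size[r]
    if (sl >= mcs && sr >= mcs) {
      c1 <- n_clusters + 1L; c2 <- n_clusters + 2L
      n_clusters <- n_clusters + 2L
      add(cid, c1, lv, sl, TRUE)
      add(cid, c2, lv, sr, TRUE)
      stack <- c(stack, list(c(l, c1)), list(c(r, c2)))
    } else if (sl < mcs && sr < mcs) {
      for (p in subtree_leaves(tree, l)) add(cid, p, lv, 1L, FALSE)
      for (p in subtree_leaves(tree, r)) add(cid, p, lv, 1L, FALSE)
    } else {
      small <- if (sl < mcs) l else r
      big <- if (sl < mcs) r else l
      for (p in subtree_leaves(tree, small)) add(cid, p, lv, 1L, FALSE)
      stack <- c(stack, list(c(big, cid)))
    }
  }
  list(parent = par_v, child = child_v, lambda = lambda_v,
       size = size_v, is_cluster = is_cluster, n_clusters = n_clusters)
}

# Excess-of-mass cluster selection (root excluded, i.e. no single-cluster
# shortcut) and hard labelling: each point joins the nearest selected
# ancestor of the cluster it detached from, or noise.
select_and_label <- function(cond, n) {
  nc <- cond$n_clusters
  birth <- rep(NA_real_, nc); birth[1] <- 0
  cluster_parent <- rep(NA_integer_, nc)
  for (i in seq_along(cond$child)) {
    if (cond$is_cluster[i]) {
      birth[cond$child[i]] <- cond$lambda[i]
      cluster_parent[cond$child[i]] <- cond$parent[i]
    }
  }
  stability <- numeric(nc)
  for (i in seq_along(cond$child)) {
    p <- cond$parent[i]
    stability[p] <- stability[p] + (cond$lambda[i] - birth[p]) * cond$size[i]
  }
  children_of <- split(cond$child[cond$is_cluster], cond$parent[cond$is_cluster])
  selected <- rep(FALSE, nc)
  sel_stab <- numeric(nc)
  for (c in rev(seq_len(nc))) {
    kids <- children_of[[as.character(c)]]
    if (is.null(kids) || length(kids) == 0) {
      if (c != 1L) selected[c] <- TRUE
      sel_stab[c] <- stability[c]
    } else {
      kid_sum <- sum(sel_stab[kids])
      if (c != 1L && stability[c] > kid_sum) {
        selected[c] <- TRUE
        # unselect all descendants
        desc <- kids
        while (length(desc) > 0) {
          selected[desc] <- FALSE
          desc <- unlist(children_of[as.character(desc)], use.names = FALSE)
        }
        sel_stab[c] <- stability[c]
      } else {
        sel_stab[c] <- kid_sum
      }
    }
  }
  labels <- rep(-1L, n)
  if (!any(selected)) return(labels)
  # map each condensed cluster to its nearest selected ancestor-or-self
  sel_anc <- rep(NA_integer_, nc)
  for (c in seq_len(nc)) {
    a <- c
    while (!is.na(a) && !selected[a]) a <- cluster_parent[a]
    sel_anc[c] <- if (is.na(a)) NA_integer_ else a
  }
  pt <- !cond$is_cluster
  lab_of_cluster <- cumsum(selected)  # consecutive ids in tree order
  for (i in which(pt)) {
    a <- sel_anc[cond$parent[i]]
    if (!is.na(a)) labels[cond$child[i]] <- lab_of_cluster[a]
  }
  labels
}
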