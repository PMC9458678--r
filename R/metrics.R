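#' Per-conformer structural metrics
#'
#' Mass-weighted center of mass, interdomain center-of-mass distances,
#' radius of gyration and maximum dimension, computed directly from atom
#' tables. All metrics are invariant under rigid-body rotation and
#' translation.
#'
#' @param conf a conformer tibble (see [as_conformer()]).
#' @param range a domain definition row (or `c(start, end)`); atoms whose
#'   `resid` falls in the inclusive range are selected.
#' @return [center_of_mass()]: a length-3 numeric (x, y, z) in Angstrom.
#' @export
center_of_mass <- function(conf, range = NULL) {
  sel <- if (is.null(range)) rep(TRUE, nrow(conf)) else select_range(conf, range)
  if (!any(sel)) abort("empty atom selection for center of mass")
  m <- conf$mass[sel]
  c(
    x = sum(m * conf$x[sel]) / sum(m),
    y = sum(m * conf$y[sel]) / sum(m),
    z = sum(m * conf$z[sel]) / sum(m)
  )
}

#' @rdname center_of_mass
#' @param a,b domain definition rows for the two centers.
#' @return [domain_distance()]: distance between the two domain centers of
#'   mass, in Angstrom.
#' @export
domain_distance <- function(conf, a, b) {
  sqrt(sum((center_of_mass(conf, a) - center_of_mass(conf, b))^2))
}

#' @rdname center_of_mass
#' @param selection optional residue range restricting the atoms used.
#' @return [radius_of_gyration()]: mass-weighted radius of gyration about the
#'   selection center of mass, in Angstrom.
#' @export
radius_of_gyration <- function(conf, selection = NULL) {
  sel <- if (is.null(selection)) rep(TRUE, nrow(conf)) else select_range(conf, selection)
  if (!any(sel)) abort("empty atom selection for radius of gyration")
  m <- conf$mass[sel]
  com <- center_of_mass(conf[sel, ], NULL)
  d2 <- (conf$x[sel] - com[1])^2 + (conf$y[sel] - com[2])^2 + (conf$z[sel] - com[3])^2
  sqrt(sum(m * d2) / sum(m))
}

#' @rdname center_of_mass
#' @return [max_dimension()]: the maximum pairwise interatomic distance
#'   (Dmax) in Angstrom.
#' @export
max_dimension <- function(conf) {
  if (nrow(conf) < 2) abort("max_dimension needs at least 2 atoms")
  max(dist(as.matrix(conf[, c("x", "y", "z")])))
}

#' Per-frame collective variables of an ensemble
#'
#' Computes, for every frame, the radius of gyration and the two interdomain
#' center-of-mass distances used as collective variables for multidomain
#' conformational landscapes: D(RING1-IBR) and D(IBR-RING2) by default.
#'
#' @param ens ensemble tibble.
#' @param domains domain definition tibble; the rows named in `cv_pairs` are
#'   used for the distances. Defaults to [hoip_domains()].
#' @param cv_pairs character matrix-like list of two domain-name pairs.
#' @return tibble with columns `frame`, `rg`, `d_<a>_<b>` per pair.
#' @export
ensemble_metrics <- function(ens, domains = hoip_domains(),
                             cv_pairs = list(c("RING1", "IBR"), c("IBR", "RING2"))) {
  frames <- ensemble_frames(ens)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    out <- tibble(frame = i, rg = radius_of_gyration(fr))
    for (p in cv_pairs) {
      da <- domains[domains$name == p[1], ]
      db <- domains[domains$name == p[2], ]
      if (nrow(da) == 0 || nrow(db) == 0) abort(paste0("unknown domain in cv_pairs: ", paste(p, collapse = "-")))
      out[[paste0("d_", tolower(p[1]), "_", tolower(p[2]))]] <- domain_distance(fr, da, db)
    }
    out
  })
  bind_rows(rows)
}

#' Pairwise C-alpha distance features
#'
#' For every frame, all pairwise distances between C-alpha atoms of the
#' selected residue ranges, flattened as the upper triangle in a fixed
#' canonical order (pairs ordered by the first then second atom index).
#' These alignment-free features capture relative domain orientations
#' without any roto-translational fitting and feed the density-based
#' structural clustering.
#'
#' @param ens ensemble tibble.
#' @param ranges domain definition tibble (one row per range).
#' @param inter_only if `TRUE`, keep only pairs whose atoms lie in different
#'   ranges (intra-domain pairs are near-constant for rigid domains).
#' @param atom_name atom name treated as C-alpha (`"CA"`).
#' @return matrix of frames x features (Angstrom), with a
#'   `feature_pairs` attribute giving the atom index pairs.
#' @export
ca_distance_features <- function(ens, ranges, inter_only = FALSE, atom_name = "CA") {
  frames <- ensemble_frames(ens)
  fr1 <- frames[[1]]
  sel <- rep(FALSE, nrow(fr1))
  dom_of <- rep(NA_integer_, nrow(fr1))
  for (r in seq_len(nrow(ranges))) {
    in_r <- select_range(fr1, ranges[r, ]) & fr1$atom == atom_name
    sel <- sel | in_r
    dom_of[in_r] <- r
  }
  idx <- which(sel)
  if (length(idx) < 2) abort("fewer than 2 C-alpha atoms selected")
  res_sel <- unique(fr1$resid[fr1$atom == atom_name &
                                Reduce(`|`, lapply(seq_len(nrow(ranges)),
                                                   function(r) select_range(fr1, ranges[r, ])))])
  covered <- vapply(seq_len(nrow(ranges)), function(r) {
    rng <- ranges[r, ]
    resids <- unique(fr1$resid[select_range(fr1, rng)])
    all(resids %in% fr1$resid[fr1$atom == atom_name])
  }, logical(1))
  if (!all(covered)) abort("selected residues missing C-alpha atoms")
  pairs <- which(upper.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
  if (inter_only) {
    keep <- dom_of[idx[pairs[, 1]]] != dom_of[idx[pairs[, 2]]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  feats <- t(vapply(frames, function(fr) {
    co <- as.matrix(fr[idx, c("x", "y", "z")])
    sqrt(rowSums((co[pairs[, 1], , drop = FALSE] - co[pairs[, 2], , drop = FALSE])^2))
  }, numeric(nrow(pairs))))
  if (nrow(pairs) == 1) feats <- matrix(feats, ncol = 1)
  attr(feats, "feature_pairs") <- cbind(idx[pairs[, 1]], idx[pairs[, 2]])
  feats
}
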