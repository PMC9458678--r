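#' Rigid-body superposition and fragment grafting
#'
#' Least-squares (Kabsch) superposition of a donor conformer onto a target
#' over the backbone atoms of an alignment residue range, followed by
#' replacement of a residue range in the target by the transformed donor
#' atoms. This is how composite multidomain models are assembled from
#' crystal-structure fragments (e.g. grafting a fully resolved C-terminal
#' domain from one structure onto the N-terminal fragment of another over a
#' shared hinge residue range).
#'
#' @param target,donor conformer tibbles.
#' @param align_range inclusive residue range (`c(start, end)` or domain
#'   row) present in both conformers with matching residue identities;
#'   superposition uses its backbone atoms (N, CA, C).
#' @param replace_range residue range whose atoms in the output come from the
#'   transformed donor; all other atoms come from the target.
#' @return a conformer tibble; attribute `"superpose_rmsd"` carries the
#'   post-fit backbone RMSD over the alignment range (Angstrom).
#' @export
superpose_and_graft <- function(target, donor, align_range, replace_range) {
  bb_names <- c("N", "CA", "C")
  sel_t <- select_range(target, align_range) & target$atom %in% bb_names
  sel_d <- select_range(donor, align_range) & donor$atom %in% bb_names
  if (!any(sel_t) || !any(sel_d)) abort("empty backbone selection in alignment range")
  key_t <- paste(target$resid[sel_t], target$atom[sel_t])
  key_d <- paste(donor$resid[sel_d], donor$atom[sel_d])
  common <- intersect(key_t, key_d)
  if (length(common) < 3) abort("alignment range shares fewer than 3 backbone atoms")
  it <- which(sel_t)[match(common, key_t)]
  id <- which(sel_d)[match(common, key_d)]
  if ("resname" %in% names(target) && "resname" %in% names(donor)) {
    if (!all(target$resname[it] == donor$resname[id])) {
      abort("residue identities differ over the alignment range")
    }
  }
  X <- as.matrix(donor[id, c("x", "y", "z")])   # mobile
  Y <- as.matrix(target[it, c("x", "y", "z")])  # fixed
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transform <- function(co) sweep(sweep(co, 2, cx) %*% t(R), 2, cy, `+`)
  donor_xyz <- transform(as.matrix(donor[, c("x", "y", "z")]))
  donor_t <- donor
  donor_t$x <- donor_xyz[, 1]; donor_t$y <- donor_xyz[, 2]; donor_t$z <- donor_xyz[, 3]
  rmsd <- sqrt(mean(rowSums((transform(X) - Y)^2)))

  keep_t <- !select_range(target, replace_range)
  take_d <- select_range(donor_t, replace_range)
  if (!any(take_d)) abort("replace range selects no donor atoms")
  rs <- if (is.data.frame(replace_range)) replace_range$start[1] else replace_range[1]
  out <- bind_rows(
    target[keep_t & target$resid < rs, , drop = FALSE],
    donor_t[take_d, , drop = FALSE],
    target[keep_t & target$resid >= rs, , drop = FALSE]
  )
  attr(out, "superpose_rmsd") <- rmsd
  out
}
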