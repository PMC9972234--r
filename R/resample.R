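#' Nearest-neighbour label resampling onto another lattice
#'
#' Each target voxel takes the label of the source voxel whose centre is
#' nearest in world coordinates, the standard way lesion identifiers are
#' carried from FLAIR space to SWI space. Labels are preserved or shrunk,
#' never invented; target voxels falling outside the source grid become
#' background.
#'
#' @param labels Source [label_volume()].
#' @param target Volume (any `chronact_volume`) defining the output lattice.
#' @return A [label_volume()] on the target lattice.
#' @export
resample_labels_nn <- function(labels, target) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(target, "chronact_volume"))
  src_aff <- labels$affine
  if (abs(det(src_aff)) < 1e-12 || abs(det(target$affine)) < 1e-12)
    stop("resample_labels_nn: singular affine")
  src_inv <- solve(src_aff)
  td <- vol_dim(target)
  # Fast path: both affines diagonal (axis-aligned, no rotation/shear).
  # The nearest source centre along each world axis is then independent,
  # so per-axis index vectors replace the full search.
  diag_only <- function(A) all(abs(A[1:3, 1:3][row(diag(3)) != col(diag(3))]) < 1e-12)
  if (diag_only(src_aff) && diag_only(target$affine)) {
    sd_ <- dim(labels$labels)
    out <- array(0L, dim = td)
    ix <- lapply(1:3, function(a) {
      w <- target$affine[a, a] * (seq_len(td[a]) - 1) + target$affine[a, 4]
      i <- as.integer(round((w - src_aff[a, 4]) / src_aff[a, a])) + 1L
      pmin(pmax(i, 1L), sd_[a])  # nearest centre: clamp at the grid edge
    })
    out[, , ] <- labels$labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    return(label_volume(out, target$spacing, target$affine))
  }
  # Search radius around the rounded continuous index: 1 suffices when the
  # source axes are orthogonal (rounding then IS the nearest centre);
  # sheared lattices get a wider net.
  A <- src_aff[1:3, 1:3]
  gram <- crossprod(A)
  off_diag <- gram[upper.tri(gram)]
  ortho <- all(abs(off_diag) < 1e-8 * max(diag(gram)))
  radius <- if (ortho) 1L else 2L
  out <- .nn_resample_labels(as.vector(labels$labels), dim(labels$labels),
                             src_aff[1:3, , drop = FALSE],
                             src_inv[1:3, , drop = FALSE],
                             as.integer(td),
                             target$affine[1:3, , drop = FALSE],
                             radius)
  label_volume(array(out, dim = td), target$spacing, target$affine)
}
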