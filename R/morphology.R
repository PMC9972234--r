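# Binary morphology and component labelling on the voxel lattice.
# Lesion connectivity is 26 (vertex); the structuring element for shell
# construction is the 6-connected (face) ball applied once per "voxel" of
# erosion/dilation. Outside the grid counts as background for both.

as_mask_array <- function(mask) {
  if (inherits(mask, "label_volume")) return(mask$labels > 0L)
  if (inherits(mask, "scalar_volume")) mask <- mask$data
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- mask != 0
  }
  storage.mode(mask) <- "logical"
  mask
}

#' Connected components of a binary mask
#'
#' 26-connectivity; components are labelled 1..K in decreasing size order
#' (ties by first raster-scan encounter), background is 0. An empty mask
#' yields an empty label set, not an error.
#'
#' @param mask Binary 3-D array, or a volume object (labels > 0 / data as
#'   0-1).
#' @param spacing,affine Geometry for the result; taken from `mask` when it
#'   is a volume object.
#' @return A [label_volume()].
#' @export
connected_components <- function(mask, spacing = NULL, affine = NULL) {
  if (inherits(mask, "chronact_volume")) {
    if (is.null(spacing)) spacing <- mask$spacing
    if (is.null(affine)) affine <- mask$affine
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  m <- as_mask_array(mask)
  lab <- .cc26_label(as.vector(m), dim(m))
  label_volume(array(lab, dim = dim(m)), spacing, affine)
}

erode6 <- function(mask, iterations = 1L) {
  m <- as_mask_array(mask)
  array(.binary_erode6(as.vector(m), dim(m), as.integer(iterations)),
        dim = dim(m))
}

dilate6 <- function(mask, iterations = 1L) {
  m <- as_mask_array(mask)
  array(.binary_dilate6(as.vector(m), dim(m), as.integer(iterations)),
        dim = dim(m))
}

#' Core / boundary-shell / perilesional-ring masks for one lesion
#'
#' The core is the lesion eroded `core_erosion` times, the shell is the
#' lesion minus its core, and the ring is the dilated lesion minus the
#' lesion with voxels belonging to other lesions excluded. The three masks
#' are pairwise disjoint. A lesion too small to survive erosion is not an
#' error: the shell is the whole lesion and `core_empty` is set.
#'
#' @param labels A [label_volume()].
#' @param lesion_id Positive integer label present in `labels`.
#' @param core_erosion,ring_dilation Iterations of the 6-connected
#'   structuring element.
#' @return List with logical arrays `core`, `shell`, `ring` (full grid
#'   size) and flag `core_empty`.
#' @export
shell_masks <- function(labels, lesion_id, core_erosion = 1L,
                        ring_dilation = 2L) {
  stopifnot(inherits(labels, "label_volume"))
  cr <- shell_masks_crop(labels$labels, lesion_id, core_erosion, ring_dilation)
  full <- function(m) {
    out <- array(FALSE, dim = dim(labels$labels))
    out[cr$i0[1]:cr$i1[1], cr$i0[2]:cr$i1[2], cr$i0[3]:cr$i1[3]] <- m
    out
  }
  list(core = full(cr$core), shell = full(cr$shell), ring = full(cr$ring),
       core_empty = cr$core_empty)
}

# Cropped workhorse: runs morphology on the lesion's padded bounding box
# only. i0/i1 are 1-based inclusive crop bounds in the full grid.
shell_masks_crop <- function(lab_arr, lesion_id, core_erosion = 1L,
                             ring_dilation = 2L) {
  idx <- which(lab_arr == lesion_id)
  if (length(idx) == 0L) stop("lesion_id ", lesion_id, " not present")
  d <- dim(lab_arr)
  ijk <- arrayInd(idx, d)
  pad <- ring_dilation + 1L
  i0 <- pmax(apply(ijk, 2, min) - pad, 1L)
  i1 <- pmin(apply(ijk, 2, max) + pad, d)
  sub <- lab_arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  les <- sub == lesion_id
  core <- if (core_erosion > 0L) erode6(les, core_erosion) else les
  shell <- les & !core
  ring <- dilate6(les, ring_dilation) & !les & (sub == 0L)
  core_empty <- !any(core)
  if (core_empty) shell <- les
  list(core = core, shell = shell, ring = ring, core_empty = core_empty,
       lesion = les, i0 = i0, i1 = i1)
}
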