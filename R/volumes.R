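#' @useDynLib chronact, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Scalar image volume
#'
#' A 3-D intensity grid with voxel spacing (mm) and a 4x4 voxel-to-world
#' affine. Used for every image channel (FLAIR-like, T1-like, SWI-like) and
#' for derived maps such as the Jacobian determinant.
#'
#' @param data 3-D numeric array of finite values.
#' @param spacing Positive length-3 numeric, mm per voxel along each axis.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). Defaults
#'   to `diag(spacing)` with a zero origin.
#' @param channel One of `"FLAIR"`, `"T1"`, `"SWI"`, `"OTHER"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                          channel = c("OTHER", "FLAIR", "T1", "SWI")) {
  channel <- match.arg(channel)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("scalar_volume: data must be a 3-D array")
  if (!all(is.finite(data))) stop("scalar_volume: data must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("scalar_volume: spacing must be 3 strictly positive numbers")
  affine <- check_affine(affine, spacing)
  structure(list(data = data, spacing = spacing, affine = affine,
                 channel = channel),
            class = c("scalar_volume", "chronact_volume"))
}

#' Labelled lesion volume
#'
#' Non-negative integer grid; 0 is background, k > 0 a lesion identifier.
#'
#' @param labels 3-D array of non-negative integers.
#' @inheritParams scalar_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), affine = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("label_volume: labels must be a 3-D array")
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("label_volume: labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("label_volume: labels must be non-negative and non-missing")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("label_volume: spacing must be 3 strictly positive numbers")
  affine <- check_affine(affine, spacing)
  structure(list(labels = labels, spacing = spacing, affine = affine),
            class = c("label_volume", "chronact_volume"))
}

#' Displacement field
#'
#' Per-voxel 3-vector of displacements in mm, stored on the baseline voxel
#' lattice as a 4-D array whose last axis has length 3. The field maps
#' baseline positions to follow-up positions, so a Jacobian determinant
#' above 1 means local expansion.
#'
#' @param vectors 4-D numeric array, last dimension 3, finite.
#' @inheritParams scalar_volume
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1), affine = NULL) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement_field: vectors must be a 4-D array with last axis 3")
  if (!all(is.finite(vectors))) stop("displacement_field: values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("displacement_field: spacing must be 3 strictly positive numbers")
  affine <- check_affine(affine, spacing)
  structure(list(vectors = vectors, spacing = spacing, affine = affine),
            class = c("displacement_field", "chronact_volume"))
}

check_affine <- function(affine, spacing) {
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  affine
}

#' @export
print.chronact_volume <- function(x, ...) {
  d <- vol_dim(x)
  cat(sprintf("<%s> %s, spacing %s mm\n", class(x)[1],
              paste(d, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Grid dimensions of a volume
#' @param vol A `chronact_volume`.
#' @return Integer length-3 vector.
#' @export
vol_dim <- function(vol) {
  if (inherits(vol, "label_volume")) dim(vol$labels)
  else if (inherits(vol, "displacement_field")) dim(vol$vectors)[1:3]
  else dim(vol$data)
}

#' Volume of one voxel in mm^3
#'
#' Uses the absolute determinant of the affine's 3x3 block, so it is correct
#' for rotated and sheared lattices, not only axis-aligned ones.
#' @param vol A `chronact_volume`.
#' @return Scalar, mm^3.
#' @export
voxel_volume <- function(vol) {
  abs(det(vol$affine[1:3, 1:3]))
}

#' Lesion identifiers present in a label volume
#' @param labels A `label_volume`.
#' @return Sorted integer vector of positive labels (possibly empty).
#' @export
label_set <- function(labels) {
  u <- sort(unique(as.vector(labels$labels)))
  u[u > 0L]
}

# world coordinates (3 x n) of 0-based voxel index columns ijk (3 x n)
voxel_to_world <- function(affine, ijk) {
  ijk <- rbind(ijk, 1)
  (affine %*% ijk)[1:3, , drop = FALSE]
}
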