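# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the dependency budget, so the format is
# handled directly: single-file .nii or .nii.gz, little- or big-endian
# headers on read (little-endian on write), datatypes uint8/int16/int32/
# uint16/float32/float64, scl_slope/scl_inter honoured, sform preferred
# over qform, qform decoded from the quaternion when it is the only code
# set. Vector fields are stored as 4-D volumes with last axis 3 (and 5-D
# NIfTI vector files with dim = (nx,ny,nz,1,3) are accepted on read).

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_header <- function(con) {
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) stop("not a NIfTI-1 file: header truncated")
  parse <- function(endian) {
    rc <- rawConnection(raw_hdr)
    on.exit(close(rc))
    h <- list()
    h$sizeof_hdr <- readBin(rc, "integer", 1, 4, endian = endian)
    invisible(readBin(rc, "raw", 36))                    # unused fields
    h$dim <- readBin(rc, "integer", 8, 2, endian = endian)
    invisible(readBin(rc, "raw", 12))                    # intent params
    h$intent_code <- readBin(rc, "integer", 1, 2, endian = endian)
    h$datatype <- readBin(rc, "integer", 1, 2, endian = endian)
    h$bitpix <- readBin(rc, "integer", 1, 2, endian = endian)
    invisible(readBin(rc, "raw", 2))                     # slice_start
    h$pixdim <- readBin(rc, "double", 8, 4, endian = endian)
    h$vox_offset <- readBin(rc, "double", 1, 4, endian = endian)
    h$scl_slope <- readBin(rc, "double", 1, 4, endian = endian)
    h$scl_inter <- readBin(rc, "double", 1, 4, endian = endian)
    invisible(readBin(rc, "raw", 28))                    # slice_end..glmin
    invisible(readBin(rc, "raw", 104))                   # descrip, aux_file
    h$qform_code <- readBin(rc, "integer", 1, 2, endian = endian)
    h$sform_code <- readBin(rc, "integer", 1, 2, endian = endian)
    h$quatern <- readBin(rc, "double", 3, 4, endian = endian)
    h$qoffset <- readBin(rc, "double", 3, 4, endian = endian)
    h$srow <- matrix(readBin(rc, "double", 12, 4, endian = endian),
                     nrow = 3, byrow = TRUE)
    invisible(readBin(rc, "raw", 16))                    # intent_name
    h$magic <- rawToChar(readBin(rc, "raw", 4)[1:3])
    h$endian <- endian
    h
  }
  h <- parse("little")
  if (h$sizeof_hdr != 348L) h <- parse("big")
  if (h$sizeof_hdr != 348L) stop("not a NIfTI-1 file: bad sizeof_hdr")
  if (!h$magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: bad magic")
  h
}

nifti_affine <- function(h) {
  if (h$sform_code > 0L) {
    rbind(h$srow, c(0, 0, 0, 1))
  } else if (h$qform_code > 0L) {
    b <- h$quatern[1]; c_ <- h$quatern[2]; d <- h$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), nrow = 3, byrow = TRUE)
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    S <- diag(c(h$pixdim[2:3], qfac * h$pixdim[4]))
    rbind(cbind(R %*% S, h$qoffset), c(0, 0, 0, 1))
  } else {
    diag(c(abs(h$pixdim[2:4]), 1))
  }
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind `"scalar"`, `"label"` or `"field"`. Fields must carry a
#'   3-component vector per voxel (4-D with last axis 3, or the 5-D NIfTI
#'   vector layout `(nx,ny,nz,1,3)`).
#' @return A [scalar_volume()], [label_volume()] or [displacement_field()]
#'   with spacing and affine taken from the header (sform preferred).
#' @export
read_volume <- function(path, kind = c("scalar", "label", "field")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  h <- read_nifti_header(con)
  dt <- NIFTI_DT[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", h$datatype)
  nd <- h$dim[1]
  dims <- h$dim[seq(2, 1 + max(nd, 1))]
  dims <- dims[dims > 0]
  ntot <- prod(dims)
  # skip any header extension up to vox_offset
  skip <- round(h$vox_offset) - 348L
  if (skip > 0) invisible(readBin(con, "raw", skip))
  vals <- readBin(con, dt$what, n = ntot, size = dt$size,
                  signed = dt$signed, endian = h$endian)
  if (length(vals) != ntot) stop("truncated NIfTI data in '", path, "'")
  slope <- h$scl_slope; inter <- h$scl_inter
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0)) {
    vals <- vals * slope + inter
  }
  spacing <- abs(h$pixdim[2:4])
  affine <- nifti_affine(h)
  if (kind == "field") {
    if (length(dims) == 5L && dims[4] == 1L && dims[5] == 3L) {
      dims <- c(dims[1:3], 3L)
    }
    if (length(dims) != 4L || dims[4] != 3L)
      stop("field file must hold a 3-vector per voxel, got dims ",
           paste(dims, collapse = "x"))
    return(displacement_field(array(vals, dim = dims), spacing, affine))
  }
  if (length(dims) != 3L) {
    if (length(dims) == 4L && dims[4] == 1L) dims <- dims[1:3]
    else stop(kind, " file must be 3-D, got dims ", paste(dims, collapse = "x"))
  }
  arr <- array(vals, dim = dims)
  if (kind == "label") {
    if (any(arr != round(arr)))
      stop("label file '", path, "' contains non-integer data")
    return(label_volume(arr, spacing, affine))
  }
  scalar_volume(arr, spacing, affine)
}

#' Write a volume as NIfTI-1
#'
#' Scalar volumes and fields are written as float64, label volumes as
#' int32; sform is set from the affine (sform_code 1), `.gz` suffixes are
#' honoured. Writing is deterministic: identical inputs give identical
#' bytes.
#'
#' @param vol A [scalar_volume()], [label_volume()] or
#'   [displacement_field()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "chronact_volume"))
  if (inherits(vol, "label_volume")) {
    data <- vol$labels; datatype <- 8L; bitpix <- 32L
    dims <- c(3L, dim(data), 1L, 1L, 1L, 1L)
  } else if (inherits(vol, "displacement_field")) {
    data <- vol$vectors; datatype <- 64L; bitpix <- 64L
    dims <- c(4L, dim(data), 1L, 1L, 1L)
  } else {
    data <- vol$data; datatype <- 64L; bitpix <- 64L
    dims <- c(3L, dim(data), 1L, 1L, 1L, 1L)
  }
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                         # sizeof_hdr
  wraw(34L)                            # data_type..session_error
  writeBin(charToRaw("r"), con)        # regular
  wraw(1L)                             # dim_info
  wi(dims, 2L)                         # dim[8]
  wf(c(0, 0, 0))                       # intent_p1..p3
  wi(0L, 2L)                           # intent_code
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)   # datatype, bitpix, slice_start
  wf(c(1, vol$spacing, 0, 0, 0, 0))    # pixdim (qfac = 1)
  wf(352)                              # vox_offset
  wf(1); wf(0)                         # scl_slope, scl_inter
  wi(0L, 2L); wraw(2L)                 # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                    # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4L)                    # glmax, glmin
  wraw(104L)                           # descrip + aux_file
  wi(0L, 2L); wi(1L, 2L)               # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))       # quaternion, qoffset
  for (r in 1:3) wf(vol$affine[r, ])   # srow_x/y/z
  wraw(16L)                            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)     # magic
  wraw(4L)                             # extension flag
  if (datatype == 8L) {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}
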