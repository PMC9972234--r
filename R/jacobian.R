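# Jacobian determinant of a displacement field.
#
# For a displacement u stored on the baseline lattice the local volume
# change of the transform x -> x + u(x) is J = det(I + Du), with Du taken
# in world (mm) units using per-axis spacing: central differences at
# interior voxels, one-sided at the grid boundary. J > 1 is expansion.

# finite difference of a 3-D array along one axis, spacing h:
# central in the interior, one-sided at the two boundary slabs
fd_axis <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 3L) stop("grid must span at least 3 voxels along every axis")
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  g <- matrix(0, nrow = n, ncol = ncol(m))
  g[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / (2 * h)
  g[1, ] <- (m[2, ] - m[1, ]) / h
  g[n, ] <- (m[n, ] - m[n - 1, ]) / h
  aperm(array(g, dim = d[perm]), order(perm))
}

# separable Gaussian smoothing of a 3-D array, sigma in mm per axis,
# replicated edges
gauss_smooth3 <- function(arr, sigma_mm, spacing) {
  for (axis in 1:3) {
    sv <- sigma_mm / spacing[axis]
    if (sv <= 0) next
    r <- max(1L, ceiling(3 * sv))
    k <- exp(-0.5 * ((-r:r) / sv)^2)
    k <- k / sum(k)
    d <- dim(arr)
    n <- d[axis]
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = n)
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(n, r), , drop = FALSE])
    sm <- matrix(0, nrow = n, ncol = ncol(m))
    for (t in seq_along(k)) {
      sm <- sm + k[t] * padded[t:(t + n - 1L), , drop = FALSE]
    }
    arr <- aperm(array(sm, dim = dm), order(perm))
  }
  arr
}

#' Jacobian determinant map of a displacement field
#'
#' @param field A [displacement_field()] on a grid of at least 3 voxels per
#'   axis.
#' @param sigma Optional Gaussian smoothing of the field components before
#'   differentiation, in mm (default 0 = none).
#' @return A [scalar_volume()] of J values on the same lattice.
#' @export
jacobian_determinant <- function(field, sigma = 0) {
  stopifnot(inherits(field, "displacement_field"))
  d <- vol_dim(field)
  if (any(d < 3L)) stop("jacobian_determinant: grid must be >= 3 voxels per axis")
  if (!all(is.finite(field$vectors))) stop("jacobian_determinant: non-finite field")
  sp <- field$spacing
  u <- lapply(1:3, function(c_) {
    comp <- field$vectors[, , , c_]
    if (sigma > 0) comp <- gauss_smooth3(comp, sigma, sp) else comp
  })
  g <- vector("list", 9L)  # g[[3*(c-1)+a]] = d u_c / d x_a
  for (c_ in 1:3) for (a in 1:3) {
    g[[3 * (c_ - 1) + a]] <- fd_axis(u[[c_]], a, sp[a])
  }
  a11 <- 1 + g[[1]]; a12 <- g[[2]];     a13 <- g[[3]]
  a21 <- g[[4]];     a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]];     a32 <- g[[8]];     a33 <- 1 + g[[9]]
  J <- a11 * (a22 * a33 - a23 * a32) -
       a12 * (a21 * a33 - a23 * a31) +
       a13 * (a21 * a32 - a22 * a31)
  scalar_volume(J, sp, field$affine)
}
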