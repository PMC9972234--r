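# Brute-force oracles, deliberately independent of the package internals:
# plain R, no shared helpers, no vectorized shortcuts.

# flood-fill (BFS) 26-connected labelling; labels ordered by decreasing size
oracle_cc26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  comp_sizes <- integer(0)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(nb))) {
        p <- ijk + nb[r, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
    comp_sizes <- c(comp_sizes, size)
  }
  ord <- order(comp_sizes, decreasing = TRUE)
  remap <- integer(nxt)
  remap[ord] <- seq_len(nxt)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# voxelwise 6-connected erosion/dilation, out of grid = background
oracle_morph6 <- function(mask, iter, erode) {
  d <- dim(mask)
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  for (t in seq_len(iter)) {
    out <- array(FALSE, d)
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      vals <- logical(6)
      for (r in 1:6) {
        p <- c(i, j, k) + off[r, ]
        vals[r] <- if (any(p < 1) || any(p > d)) FALSE else mask[p[1], p[2], p[3]]
      }
      out[i, j, k] <- if (erode) mask[i, j, k] && all(vals)
                      else mask[i, j, k] || any(vals)
    }
    mask <- out
  }
  mask
}

# exhaustive nearest-source-centre resampling in world coordinates
oracle_nn_resample <- function(lab, tgt_dim, tgt_affine) {
  sd_ <- dim(lab$labels)
  src_ijk <- as.matrix(expand.grid(0:(sd_[1] - 1), 0:(sd_[2] - 1),
                                   0:(sd_[3] - 1)))
  src_w <- t(lab$affine[1:3, 1:3] %*% t(src_ijk) + lab$affine[1:3, 4])
  out <- array(0L, tgt_dim)
  for (k in 0:(tgt_dim[3] - 1)) for (j in 0:(tgt_dim[2] - 1))
    for (i in 0:(tgt_dim[1] - 1)) {
      w <- tgt_affine[1:3, 1:3] %*% c(i, j, k) + tgt_affine[1:3, 4]
      d2 <- colSums((t(src_w) - as.vector(w))^2)
      out[i + 1, j + 1, k + 1] <- lab$labels[which.min(d2)]
    }
  out
}

# entrywise gradient assembly + per-voxel 3x3 determinants
oracle_jacobian <- function(vec, sp) {
  d <- dim(vec)[1:3]
  gr <- function(arr, axis, at) {
    idx <- function(p) { q <- at; q[axis] <- p; arr[q[1], q[2], q[3]] }
    n <- d[axis]
    if (at[axis] == 1) (idx(2) - idx(1)) / sp[axis]
    else if (at[axis] == n) (idx(n) - idx(n - 1)) / sp[axis]
    else (idx(at[axis] + 1) - idx(at[axis] - 1)) / (2 * sp[axis])
  }
  J <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    M <- diag(3)
    for (c_ in 1:3) for (a in 1:3) {
      M[c_, a] <- M[c_, a] + gr(vec[, , , c_], a, c(i, j, k))
    }
    J[i, j, k] <- det(M)
  }
  J
}

# z-score by direct summation
oracle_z <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  (x - m) / s
}

# Spearman rho by the tie-free rank formula
oracle_spearman <- function(x, y) {
  dd <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(dd^2) / (n * (n^2 - 1))
}

# small geometric fixtures ---------------------------------------------

cube_labels <- function(dim = c(9, 9, 9), lo = 3, hi = 7, spacing = c(1, 1, 1)) {
  a <- array(0L, dim)
  a[lo:hi, lo:hi, lo:hi] <- 1L
  label_volume(a, spacing)
}

# axis-aligned affine displacement field u(x) = (A - I) x on a grid
affine_field <- function(A, dims, sp) {
  g <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                             k = 0:(dims[3] - 1)))
  xyz <- t(t(g) * sp)
  u <- xyz %*% t(A - diag(3))
  vec <- array(0, c(dims, 3))
  for (c_ in 1:3) vec[, , , c_] <- array(u[, c_], dims)
  displacement_field(vec, sp)
}
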