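# Internal numeric helpers shared across modules.

#' Signed frequency indices for an axis of length n
#'
#' Returns the integer frequency index h for each FFT output slot, in the
#' order base R's fft() stores them: 0, 1, ..., then negative frequencies.
#' For even n the range is -n/2 .. n/2-1; for odd n, -(n-1)/2 .. (n-1)/2.
#' @keywords internal
#' @noRd
freq_index <- function(n) {
  h <- 0:(n - 1L)
  h - n * (h >= ceiling(n / 2))
}

# Three full-grid arrays of signed frequency indices (voxel units).
freq_index_grids <- function(shape) {
  hx <- freq_index(shape[1])
  hy <- freq_index(shape[2])
  hz <- freq_index(shape[3])
  list(
    hx = array(hx, dim = shape),
    hy = array(rep(hy, each = shape[1]), dim = shape),
    hz = array(rep(hz, each = shape[1] * shape[2]), dim = shape)
  )
}

# |s| in 1/Angstrom for every reciprocal-lattice point.
freq_magnitude <- function(shape, pixel_size) {
  g <- freq_index_grids(shape)
  sx <- g$hx / (shape[1] * pixel_size[1])
  sy <- g$hy / (shape[2] * pixel_size[2])
  sz <- g$hz / (shape[3] * pixel_size[3])
  sqrt(sx^2 + sy^2 + sz^2)
}

# Circular shift of a 3D array by integer offsets (positive = towards
# higher indices), used to re-centre maps before Fourier interpolation.
circshift3 <- function(a, shift) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) {
    s <- ((shift[k]) %% d[k])
    if (s == 0) seq_len(d[k]) else c((d[k] - s + 1):d[k], 1:(d[k] - s))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Periodic trilinear interpolation on a 3D array
#'
#' @param a numeric or complex 3D array.
#' @param pts n x 3 matrix of 0-based fractional indices.
#' @param grad if TRUE also return the gradient of the interpolant with
#'   respect to each index coordinate (exact for the trilinear form).
#' @return list(value, and optionally gx, gy, gz), each length n.
#' @keywords internal
#' @noRd
trilinear_periodic <- function(a, pts, grad = FALSE) {
  d <- dim(a)
  f0 <- floor(pts)
  fr <- pts - f0
  ix0 <- (f0[, 1] %% d[1]) + 1L; iy0 <- (f0[, 2] %% d[2]) + 1L; iz0 <- (f0[, 3] %% d[3]) + 1L
  ix1 <- (ix0 %% d[1]) + 1L;     iy1 <- (iy0 %% d[2]) + 1L;     iz1 <- (iz0 %% d[3]) + 1L
  dx <- fr[, 1]; dy <- fr[, 2]; dz <- fr[, 3]

  c000 <- a[cbind(ix0, iy0, iz0)]; c100 <- a[cbind(ix1, iy0, iz0)]
  c010 <- a[cbind(ix0, iy1, iz0)]; c110 <- a[cbind(ix1, iy1, iz0)]
  c001 <- a[cbind(ix0, iy0, iz1)]; c101 <- a[cbind(ix1, iy0, iz1)]
  c011 <- a[cbind(ix0, iy1, iz1)]; c111 <- a[cbind(ix1, iy1, iz1)]

  # collapse x, then y, then z
  cx00 <- c000 + dx * (c100 - c000)
  cx10 <- c010 + dx * (c110 - c010)
  cx01 <- c001 + dx * (c101 - c001)
  cx11 <- c011 + dx * (c111 - c011)
  cxy0 <- cx00 + dy * (cx10 - cx00)
  cxy1 <- cx01 + dy * (cx11 - cx01)
  val <- cxy0 + dz * (cxy1 - cxy0)
  out <- list(value = val)
  if (grad) {
    gx00 <- c100 - c000; gx10 <- c110 - c010; gx01 <- c101 - c001; gx11 <- c111 - c011
    gxy0 <- gx00 + dy * (gx10 - gx00)
    gxy1 <- gx01 + dy * (gx11 - gx01)
    out$gx <- gxy0 + dz * (gxy1 - gxy0)
    cy0 <- cx10 - cx00
    cy1 <- cx11 - cx01
    out$gy <- cy0 + dz * (cy1 - cy0)
    out$gz <- cxy1 - cxy0
  }
  out
}

# Non-periodic trilinear interpolation; points outside the grid give NA.
# Corners with zero interpolation weight are ignored, so an NA voxel only
# propagates when it actually contributes.
trilinear_bounded <- function(a, pts) {
  d <- dim(a)
  ok <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= d[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= d[3] - 1
  val <- rep(NA_real_, nrow(pts))
  if (any(ok)) {
    p <- pts[ok, , drop = FALSE]
    f0 <- floor(p)
    fr <- p - f0
    i0 <- f0 + 1L
    i1 <- pmin(f0 + 2L, matrix(rep(d, each = nrow(p)), ncol = 3))
    wx <- fr[, 1]; wy <- fr[, 2]; wz <- fr[, 3]
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) wx else 1 - wx) * (if (cy) wy else 1 - wy) *
        (if (cz) wz else 1 - wz)
      ii <- cbind(
        if (cx) i1[, 1] else i0[, 1],
        if (cy) i1[, 2] else i0[, 2],
        if (cz) i1[, 3] else i0[, 3]
      )
      cv <- a[ii]
      acc <- acc + ifelse(w == 0, 0, w * cv)
    }
    val[ok] <- acc
  }
  list(value = val, inside = ok)
}

# Periodic trilinear interpolation of several arrays (same grid) at the
# same points, sharing the corner-index computation. Returns a list of
# value vectors in the order of `arrays`.
trilinear_periodic_multi <- function(arrays, pts) {
  d <- dim(arrays[[1]])
  f0 <- floor(pts)
  fr <- pts - f0
  ix0 <- (f0[, 1] %% d[1]) + 1L; iy0 <- (f0[, 2] %% d[2]) + 1L; iz0 <- (f0[, 3] %% d[3]) + 1L
  ix1 <- (ix0 %% d[1]) + 1L;     iy1 <- (iy0 %% d[2]) + 1L;     iz1 <- (iz0 %% d[3]) + 1L
  dx <- fr[, 1]; dy <- fr[, 2]; dz <- fr[, 3]
  corners <- list(
    cbind(ix0, iy0, iz0), cbind(ix1, iy0, iz0), cbind(ix0, iy1, iz0),
    cbind(ix1, iy1, iz0), cbind(ix0, iy0, iz1), cbind(ix1, iy0, iz1),
    cbind(ix0, iy1, iz1), cbind(ix1, iy1, iz1)
  )
  w <- list(
    (1 - dx) * (1 - dy) * (1 - dz), dx * (1 - dy) * (1 - dz),
    (1 - dx) * dy * (1 - dz), dx * dy * (1 - dz),
    (1 - dx) * (1 - dy) * dz, dx * (1 - dy) * dz,
    (1 - dx) * dy * dz, dx * dy * dz
  )
  lapply(arrays, function(a) {
    acc <- 0
    for (k in 1:8) acc <- acc + w[[k]] * a[corners[[k]]]
    acc
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
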