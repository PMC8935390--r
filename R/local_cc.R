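# Kernel-weighted local correlation.
#
# A soft spherical kernel (flat plateau of radius r0, raised-cosine falloff
# to zero at r1) defines a moving window. Local means, variances and the
# covariance of two maps under that window are evaluated by FFT convolution,
# and their ratio gives a per-voxel Pearson correlation: between half maps
# it measures local signal-to-noise; between an observed map and a
# model-derived map it measures local map-model agreement.

#' Build a soft spherical kernel
#'
#' Weight 1/Z inside radius r0, raised-cosine
#' \code{(1/2Z)(1 + cos(pi (|x| - r0)/(r1 - r0)))} between r0 and r1, zero
#' beyond r1. Weights are evaluated at voxel centres and Z is the discrete
#' sum, so the kernel sums to exactly 1.
#'
#' @param r0 plateau radius in voxels (>= 0).
#' @param r1 outer radius in voxels; default \code{r0 + 2} (two voxels of
#'   soft edge).
#' @return object of class \code{cc_kernel}: cubic \code{weights} array of
#'   side \code{2*ceiling(r1) + 1}, plus \code{r0}, \code{r1}.
#' @export
build_kernel <- function(r0, r1 = r0 + 2) {
  if (r0 < 0) stop("build_kernel: r0 must be >= 0")
  if (r1 <= r0) stop("build_kernel: r1 must exceed r0")
  rad <- ceiling(r1)
  ax <- (-rad):rad
  n <- length(ax)
  dx <- array(ax, c(n, n, n))
  dy <- aperm(dx, c(2, 1, 3))
  dz <- aperm(dx, c(3, 2, 1))
  r <- sqrt(dx^2 + dy^2 + dz^2)
  w <- array(0, dim(r))
  w[r <= r0] <- 1
  edge <- r > r0 & r < r1
  w[edge] <- 0.5 * (1 + cos(pi * (r[edge] - r0) / (r1 - r0)))
  w <- w / sum(w)
  structure(list(weights = w, r0 = r0, r1 = r1, radius = rad),
    class = "cc_kernel")
}

# kernel embedded on a full grid with its centre at voxel (0,0,0), wrapped,
# so FFT convolution evaluates the window correlation at every voxel.
kernel_on_grid <- function(kernel, shape) {
  if (any(dim(kernel$weights) > shape)) {
    stop("kernel larger than the map grid")
  }
  k <- array(0, shape)
  rad <- kernel$radius
  for (ox in (-rad):rad) {
    ix <- ox %% shape[1] + 1L
    iy <- ((-rad):rad) %% shape[2] + 1L
    iz <- ((-rad):rad) %% shape[3] + 1L
    k[ix, iy, iz] <- kernel$weights[ox + rad + 1, , ]
  }
  k
}

conv_fft <- function(khat, a) {
  Re(stats::fft(khat * stats::fft(a), inverse = TRUE)) / length(a)
}

#' Local first and second moments of a map pair under a kernel
#'
#' Evaluates the kernel-weighted local means, variances and covariance at
#' every voxel via the convolution theorem (circular convolution on the FFT
#' grid; edge voxels therefore mix density from opposite faces).
#'
#' @param map1,map2 [voxel_map()]s on the same grid.
#' @param kernel a [build_kernel()] kernel.
#' @return object of class \code{local_moments} with per-voxel arrays
#'   \code{mean1}, \code{mean2}, \code{var1}, \code{var2}, \code{cov12}
#'   (variances clamped at 0).
#' @export
local_moments <- function(map1, map2, kernel) {
  stopifnot_voxel_map(map1); stopifnot_voxel_map(map2)
  if (!all(dim(map1$data) == dim(map2$data))) {
    stop("local_moments: maps are on different grids")
  }
  a1 <- map1$data; a2 <- map2$data
  khat <- stats::fft(kernel_on_grid(kernel, dim(a1)))
  m1 <- conv_fft(khat, a1)
  m2 <- conv_fft(khat, a2)
  v1 <- pmax(conv_fft(khat, a1 * a1) - m1 * m1, 0)
  v2 <- pmax(conv_fft(khat, a2 * a2) - m2 * m2, 0)
  cv <- conv_fft(khat, a1 * a2) - m1 * m2
  structure(list(mean1 = m1, mean2 = m2, var1 = v1, var2 = v2, cov12 = cv,
    shape = dim(a1)), class = "local_moments")
}

#' Local correlation map from moments
#'
#' Per-voxel Pearson correlation \code{cov12 / sqrt(var1 var2)}, clipped to
#' [-1, 1]. Voxels where either local variance falls at or below the floor
#' (flat solvent) are undefined and set NA.
#'
#' @param m a [local_moments()] object.
#' @param var_floor variance floor; default \code{1e-12 *} the geometric
#'   mean of the two global variances, guarding 0/0 in flat regions.
#' @param kind one of "half", "full", "map_model"; recorded on the result.
#' @return object of class \code{cc_map} with \code{values} (3D array, NA
#'   where undefined) and \code{kind}.
#' @export
cc_from_moments <- function(m, var_floor = NULL, kind = "half") {
  stopifnot(inherits(m, "local_moments"))
  var_floor <- var_floor %||%
    (1e-12 * sqrt(max(mean(m$var1), 1e-300) * max(mean(m$var2), 1e-300)))
  vals <- array(NA_real_, m$shape)
  ok <- m$var1 > var_floor & m$var2 > var_floor
  vals[ok] <- m$cov12[ok] / sqrt(m$var1[ok] * m$var2[ok])
  vals[ok] <- pmin(pmax(vals[ok], -1), 1)
  structure(list(values = vals, kind = kind), class = "cc_map")
}

#' Convert a half-map local correlation to the full-map scale
#'
#' Voxel-wise \code{2 c / (1 + c)}; c = -1 maps to NA. Strictly increasing,
#' fixes 0 and 1.
#'
#' @param cc a \code{cc_map} of kind "half".
#' @return a \code{cc_map} of kind "full".
#' @export
cc_half_to_full <- function(cc) {
  stopifnot(inherits(cc, "cc_map"))
  if (!identical(cc$kind, "half")) {
    stop("cc_half_to_full: input must be a half-map correlation")
  }
  v <- cc$values
  out <- 2 * v / (1 + v)
  out[!is.na(v) & v <= -1] <- NA_real_
  structure(list(values = out, kind = "full"), class = "cc_map")
}

#' Local half-map correlation (convenience wrapper)
#'
#' @param half1,half2 the two half maps as [voxel_map()]s.
#' @param kernel a [build_kernel()] kernel.
#' @param var_floor passed to [cc_from_moments()].
#' @return a \code{cc_map} of kind "half".
#' @export
cc_halfmap <- function(half1, half2, kernel, var_floor = NULL) {
  cc_from_moments(local_moments(half1, half2, kernel), var_floor, "half")
}

#' Local map-versus-model correlation
#'
#' Correlates a full map with a model-derived map under the kernel. Both
#' inputs must have been normalized and FSC-weighted
#' ([normalize_and_weight()]) so that the result is on the same scale as
#' CCfull and the overfitting diagnostic CCmap,model <= CCfull applies.
#'
#' @param fullmap,modelmap [voxel_map()]s produced by inverse-transforming
#'   normalized+weighted coefficients (carrying the \code{weighted}
#'   attribute), on one grid.
#' @param kernel a [build_kernel()] kernel.
#' @param var_floor passed to [cc_from_moments()].
#' @param force skip the weighted-input check (not recommended).
#' @return a \code{cc_map} of kind "map_model".
#' @export
cc_map_model <- function(fullmap, modelmap, kernel, var_floor = NULL,
                         force = FALSE) {
  if (!force) {
    w1 <- isTRUE(attr(fullmap, "weighted"))
    w2 <- isTRUE(attr(modelmap, "weighted"))
    if (!(w1 && w2)) {
      stop("cc_map_model: inputs are not normalized+weighted maps; ",
        "pass maps built with normalize_and_weight() or set force = TRUE")
    }
  }
  cc_from_moments(local_moments(fullmap, modelmap, kernel), var_floor,
    "map_model")
}

#' Interpolate a correlation map at atomic positions
#'
#' Trilinear interpolation of the correlation values at each atom. Atoms
#' outside the grid, or whose interpolation cell touches an undefined (NA)
#' correlation voxel, are flagged and given NA rather than clamped.
#'
#' @param cc a \code{cc_map}.
#' @param atoms data.frame from [read_atoms()].
#' @param map the [voxel_map()] the correlation was computed on (supplies
#'   grid geometry).
#' @return data.frame with columns \code{cc} and logical \code{flagged}.
#' @export
atom_cc <- function(cc, atoms, map) {
  stopifnot(inherits(cc, "cc_map"))
  pts <- pos_to_index(map, cbind(atoms$x, atoms$y, atoms$z))
  res <- trilinear_bounded(cc$values, pts)
  data.frame(cc = res$value, flagged = !res$inside | !is.finite(res$value))
}

# carry normalize_and_weight's flag from Fourier space to real space
#' Inverse-transform normalized coefficients keeping the weighting flag
#' @param fm a \code{fourier_map} from [normalize_and_weight()].
#' @return a [voxel_map()] with the \code{weighted}/\code{normalized}
#'   attributes preserved.
#' @export
weighted_real_map <- function(fm) {
  vm <- inverse_fft(fm)
  attr(vm, "normalized") <- attr(fm, "normalized")
  attr(vm, "weighted") <- attr(fm, "weighted")
  vm
}
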