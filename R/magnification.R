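# Relative magnification (pixel-size) refinement.
#
# A map collected with a mis-calibrated pixel size appears uniformly
# rescaled relative to a reference. The scale enters the overlay likelihood
# by sampling the moving map's spectrum at scaled frequencies (a diagonal
# "rotation" matrix with one magnification parameter), so it can be refined
# with the same cross-term machinery: alternate a rigid fit with a 1-D
# search over the scalar until the functional converges.

#' Resample a map onto a target grid geometry
#'
#' When the physical extents agree, resampling is done by Fourier
#' cropping/padding (band-limited, exact for band-limited content). For
#' incommensurate grids (different pixel sizes and extents) the map is
#' interpolated in real space at the target voxel centres, treating voxel
#' values as samples of a smooth density; upsampling beyond the stored
#' Nyquist limit is allowed (the added band is empty) and logged.
#'
#' @param map a [voxel_map()].
#' @param shape target grid dimensions.
#' @param pixel_size target pixel size in Angstrom.
#' @param origin target origin; default the source origin.
#' @return a [voxel_map()] with the requested geometry.
#' @export
resample_to_grid <- function(map, shape, pixel_size, origin = NULL) {
  stopifnot_voxel_map(map)
  pixel_size <- rep_len(as.numeric(pixel_size), 3L)
  origin <- origin %||% map$origin
  src_shape <- dim(map$data)
  if (all(shape == src_shape) &&
      all(abs(pixel_size - map$pixel_size) < 1e-9 * pixel_size) &&
      all(abs(origin - map$origin) < 1e-9)) {
    return(map)
  }
  same_extent <- all(abs(shape * pixel_size - src_shape * map$pixel_size) <
    1e-6 * src_shape * map$pixel_size) && all(abs(origin - map$origin) < 1e-9)
  if (same_extent) {
    Fsrc <- stats::fft(map$data)
    Fdst <- array(0i, shape)
    hs <- lapply(1:3, function(k) freq_index(src_shape[k]))
    hd <- lapply(1:3, function(k) freq_index(shape[k]))
    # copy every destination frequency present in the source band
    keep <- lapply(1:3, function(k) {
      m <- match(hd[[k]], hs[[k]])
      list(dst = which(!is.na(m)), src = m[!is.na(m)])
    })
    Fdst[keep[[1]]$dst, keep[[2]]$dst, keep[[3]]$dst] <-
      Fsrc[keep[[1]]$src, keep[[2]]$src, keep[[3]]$src]
    if (any(shape > src_shape)) {
      message("resample_to_grid: upsampling beyond stored Nyquist; new band is zero-filled")
    }
    out <- Re(stats::fft(Fdst, inverse = TRUE)) / prod(src_shape)
    return(voxel_map(out, pixel_size, origin))
  }
  # general case: grids are axis-aligned, so the trigonometric interpolant
  # of the periodic band-limited source can be evaluated exactly and
  # separably: one Dirichlet (periodic sinc) interpolation matrix per axis
  idx_ax <- lapply(1:3, function(k) {
    (origin[k] + (0:(shape[k] - 1)) * pixel_size[k] - map$origin[k]) /
      map$pixel_size[k]
  })
  out <- map$data
  for (k in 1:3) {
    n <- src_shape[k]
    M <- outer(idx_ax[[k]], 0:(n - 1), function(x, j) {
      dirichlet_kernel(x - j, n)
    })
    # zero targets outside the physical source extent instead of wrapping
    outside <- idx_ax[[k]] < -0.5 | idx_ax[[k]] > n - 0.5
    M[outside, ] <- 0
    d <- dim(out)
    rest <- setdiff(1:3, k)
    flat <- matrix(aperm(out, c(k, rest)), d[k])
    res <- M %*% flat
    out <- aperm(array(res, c(shape[k], d[rest])), order(c(k, rest)))
  }
  voxel_map(out, pixel_size, origin)
}

# Axis-aligned scale-and-shift of a 3D array about the grid centre,
# evaluated exactly through separable Dirichlet interpolation:
# out(x) = arr(c + (x - c - t)/s). Being exact for the band-limited
# interpolant, it carries no scale-dependent smoothing, which matters when
# a scalar magnification is being refined.
scale_shift_dirichlet <- function(arr, s, tvox, ctr) {
  d <- dim(arr)
  out <- arr
  for (k in 1:3) {
    pos <- ctr[k] + ((0:(d[k] - 1)) - ctr[k] - tvox[k]) / s
    M <- outer(pos, 0:(d[k] - 1), function(x, j) dirichlet_kernel(x - j, d[k]))
    rest <- setdiff(1:3, k)
    dd <- dim(out)
    flat <- matrix(aperm(out, c(k, rest)), dd[k])
    out <- aperm(array(M %*% flat, c(d[k], dd[rest])), order(c(k, rest)))
  }
  out
}

# Dirichlet (periodic sinc) kernel: the exact interpolator of a periodic
# band-limited signal sampled at n points (even-n form).
dirichlet_kernel <- function(x, n) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  xx <- x[nz]
  v <- sin(pi * xx) / (n * tan(pi * xx / n))
  v[!is.finite(v)] <- 0   # poles of tan at the half-period
  out[nz] <- v
  out
}

#' Principal-axes pre-alignment of two maps
#'
#' Diagonalizes the density-weighted second-moment (variance-covariance)
#' matrices of both maps (negative density clipped at zero) and returns the
#' proper rotation mapping the moving principal axes onto the reference
#' axes; of the four proper sign assignments the one maximizing real-space
#' overlap is kept. Near-degenerate moment spectra (ratio of adjacent
#' eigenvalues below \code{degeneracy}) cannot orient the map; the identity
#' is returned with \code{degenerate = TRUE}.
#'
#' @param ref,moving [voxel_map()]s on one grid.
#' @param degeneracy eigenvalue ratio below which axes are ambiguous.
#' @return list(\code{transform} = [rigid_transform()], \code{degenerate}).
#' @export
pca_prealign <- function(ref, moving, degeneracy = 1.05) {
  stopifnot_voxel_map(ref); stopifnot_voxel_map(moving)
  moments <- function(vm) {
    w <- pmax(vm$data, 0)
    tot <- sum(w)
    if (tot <= 0) stop("pca_prealign: map has no positive density")
    shape <- dim(vm$data)
    ax <- (0:(shape[1] - 1)) * vm$pixel_size[1]
    ay <- (0:(shape[2] - 1)) * vm$pixel_size[2]
    az <- (0:(shape[3] - 1)) * vm$pixel_size[3]
    gx <- array(ax, shape); gy <- array(rep(ay, each = shape[1]), shape)
    gz <- array(rep(az, each = shape[1] * shape[2]), shape)
    mu <- c(sum(w * gx), sum(w * gy), sum(w * gz)) / tot
    xs <- list(gx - mu[1], gy - mu[2], gz - mu[3])
    S <- matrix(0, 3, 3)
    for (i in 1:3) for (j in i:3) {
      S[i, j] <- S[j, i] <- sum(w * xs[[i]] * xs[[j]]) / tot
    }
    S
  }
  e_ref <- eigen(moments(ref), symmetric = TRUE)
  e_mov <- eigen(moments(moving), symmetric = TRUE)
  ratios <- c(e_mov$values[1] / e_mov$values[2],
    e_mov$values[2] / max(e_mov$values[3], 1e-30))
  if (any(!is.finite(ratios)) || any(ratios < degeneracy)) {
    return(list(transform = rigid_transform(), degenerate = TRUE))
  }
  Vr <- e_ref$vectors; Vm <- e_mov$vectors
  if (det(Vr) < 0) Vr[, 3] <- -Vr[, 3]
  if (det(Vm) < 0) Vm[, 3] <- -Vm[, 3]
  best <- NULL; best_score <- -Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))     # proper sign flips only
    R <- Vr %*% S %*% t(Vm)
    cand <- rigid_transform(R)
    rot <- apply_transform_to_map(moving, cand)
    score <- stats::cor(as.vector(rot$data), as.vector(ref$data))
    if (is.finite(score) && score > best_score) {
      best_score <- score; best <- cand
    }
  }
  list(transform = best, degenerate = FALSE)
}

#' Refine the relative magnification of a map against a reference
#'
#' Alternates a rigid overlay fit with a one-dimensional refinement of the
#' scalar magnification (frequencies of the moving map scaled by the
#' current correction factor in the likelihood cross-term) until the joint
#' functional converges. If the moving map is not on the reference grid it
#' is resampled first.
#'
#' @param ref reference [voxel_map()] (an observed map or a model-derived
#'   map).
#' @param moving the map whose magnification is sought.
#' @param init initial [rigid_transform()] (e.g. from [pca_prealign()]).
#' @param resolution high-resolution cutoff in Angstrom; default Nyquist.
#' @param max_cycles maximum outer (rigid + magnification) cycles.
#' @param tol relative functional-change convergence threshold.
#' @param search_halfwidth half-width of each 1-D magnification bracket.
#' @return object of class \code{mag_fit}: \code{magnification} (the moving
#'   map's scale relative to the reference; 1 = none),
#'   \code{error_percent} = (magnification - 1) * 100,
#'   \code{corrected_pixel_size} (the moving map's pixel size divided by
#'   the magnification), the rigid \code{transform} (whose
#'   \code{magnification} field holds the correction factor), \code{nll},
#'   \code{converged}, and per-bin \code{fsc_before}/\code{fsc_after}
#'   against the reference.
#' @export
refine_magnification <- function(ref, moving, init = rigid_transform(),
                                 resolution = NULL, max_cycles = 20,
                                 tol = 1e-6, search_halfwidth = 0.03) {
  stopifnot_voxel_map(ref); stopifnot_voxel_map(moving)
  moving_pixel <- moving$pixel_size[1]
  if (!all(dim(moving$data) == dim(ref$data)) ||
      any(abs(moving$pixel_size - ref$pixel_size) > 1e-9 * ref$pixel_size)) {
    moving_on_ref <- resample_to_grid(moving, dim(ref$data), ref$pixel_size,
      ref$origin)
  } else {
    moving_on_ref <- moving
  }
  res_full <- resolution %||% (2 * max(ref$pixel_size))
  # 3x band-limited upsampling of the moving map: the residual trilinear
  # attenuation grows with the distance of the sampling scale from the
  # lattice and would otherwise pull the magnification estimate toward 1
  prep <- fit_prep(ref, moving_on_ref, resolution = res_full, upsample = 3L)
  R <- init$R
  tvox <- init$translation / prep$pixel
  sscale <- 1 / init$magnification   # correction factor applied to moving
  nll <- NA_real_
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    # (a) rigid update at fixed magnification. Only the first cycles: the
    # cross-term's pose optimum and the profile functional's pose optimum
    # differ slightly, and alternating them indefinitely ping-pongs the
    # translation; once the rotation has settled the (s, t) polish below
    # owns the pose.
    if (cycle <= 2) {
      tmov <- fit_resample(prep, R, tvox, sscale)
      wt <- fit_weights(prep, tmov)
      if (all(wt$w_bin == 0)) stop("refine_magnification: no shared signal")
      step <- fit_inner(prep, wt$fstat, R, tvox, mag = sscale)
      R <- step$R
      tvox <- step$tvox
    }
    # (b) scalar magnification update at fixed pose. Two requirements: the
    # functional must be re-normalized per shell at every candidate scale
    # (rescaling redistributes spectral power across shells, so the
    # fixed-weight cross-term is not a valid score), and the candidate
    # scale must be applied without scale-dependent interpolation
    # smoothing (which pulls the estimate toward 1). The transform
    # factorizes as scale+shift after a pure rotation, so the rotation is
    # resampled once and the axis-aligned part is exact Dirichlet.
    rotated <- fit_resample(prep, R, c(0, 0, 0), 1)
    lo <- max(0.8, sscale - search_halfwidth)
    hi <- min(1.25, sscale + search_halfwidth)
    obj_m <- function(s) {
      fit_score_prof(prep, scale_shift_dirichlet(rotated, s, tvox, prep$ctr))
    }
    # coarse grid first: the functional can carry small-scale roughness
    # where shell correlations saturate, which traps a pure golden search
    sgrid <- seq(lo, hi, length.out = 13)
    vg <- vapply(sgrid, obj_m, numeric(1))
    # flat plateaus happen when shell correlations saturate (noise-free
    # self-comparisons): among ties, prefer the grid point closest to the
    # current scale so a degenerate search leaves the estimate alone
    ties <- which(vg <= min(vg) + 1e-9 * abs(min(vg)))
    ib <- ties[which.min(abs(sgrid[ties] - sscale))]
    blo <- sgrid[max(1, ib - 1)]; bhi <- sgrid[min(length(sgrid), ib + 1)]
    om <- stats::optimize(obj_m, c(blo, bhi), tol = 1e-6)
    # on a flat (saturated) stretch the golden search lands anywhere in
    # the bracket; prefer the grid point nearest the current scale when
    # the refinement bought nothing
    if (abs(om$objective - vg[ib]) <= 1e-7 * abs(vg[ib]) &&
        abs(sgrid[ib] - sscale) < abs(om$minimum - sscale)) {
      om <- list(minimum = sgrid[ib], objective = vg[ib])
    }
    sscale <- om$minimum
    # joint polish of scale and translation on the same functional: scale
    # trades against translation along a flat ridge when the content
    # centroid is off-centre, and holding t fixed would leave the
    # alternation at a biased fixed point
    obj_st <- function(p) {
      if (p[1] < lo || p[1] > hi) return(Inf)
      fit_score_prof(prep,
        scale_shift_dirichlet(rotated, p[1], p[2:4], prep$ctr))
    }
    op <- stats::optim(c(sscale, tvox), obj_st, method = "Nelder-Mead",
      control = list(maxit = 150, reltol = 1e-10,
        parscale = c(0.002, 0.1, 0.1, 0.1)))
    # a degenerate (saturated) profile is flat around the optimum; keep
    # the current state unless the polish made a real improvement, and
    # keep the current scale whenever the improvement came from the
    # translation alone (the simplex drifts freely along a flat scale)
    if (op$value < om$objective - 1e-8 * abs(om$objective)) {
      t_new <- op$par[2:4]
      v_keep_s <- obj_st(c(sscale, t_new))
      if (v_keep_s <= op$value + 1e-9 * abs(op$value)) {
        tvox <- t_new
        om$objective <- v_keep_s
      } else {
        sscale <- op$par[1]
        tvox <- t_new
        om$objective <- op$value
      }
    }
    if (sscale <= 0.8 + 1e-6 || sscale >= 1.25 - 1e-6) {
      stop("refine_magnification: magnification hit the search bound [0.8, 1.25]; ",
        "check the pre-alignment")
    }
    new_nll <- om$objective
    if (is.finite(nll) && abs(new_nll - nll) <= tol * abs(nll)) {
      converged <- TRUE
      nll <- new_nll
      break
    }
    nll <- new_nll
  }
  final <- rigid_transform(R, tvox * prep$pixel, magnification = sscale)
  f_ref <- forward_fft(ref)
  f_mov <- forward_fft(moving_on_ref)
  fsc_before <- fsc(f_ref, f_mov, prep$shells)
  corrected <- scale_shift_dirichlet(fit_resample(prep, R, c(0, 0, 0), 1),
    sscale, tvox, prep$ctr)
  fsc_after <- fsc(f_ref, as_fourier_map(stats::fft(corrected), f_mov),
    prep$shells)
  magnification <- 1 / sscale
  structure(
    list(
      magnification = magnification,
      error_percent = (magnification - 1) * 100,
      corrected_pixel_size = moving_pixel / magnification,
      transform = final, nll = nll, converged = converged,
      cycles = cycle, fsc_before = fsc_before, fsc_after = fsc_after,
      shells = prep$shells
    ),
    class = "mag_fit"
  )
}

#' @export
print.mag_fit <- function(x, ...) {
  cat(sprintf(
    "<mag_fit: magnification %.5f (%+.3f%%), corrected pixel %.5f A, %s in %d cycles>\n",
    x$magnification, x$error_percent, x$corrected_pixel_size,
    if (x$converged) "converged" else "NOT converged", x$cycles
  ))
  invisible(x)
}
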