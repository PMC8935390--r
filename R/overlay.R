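# Likelihood-based rigid-body map superposition.
#
# One map is static, the other moves. With per-shell covariances fixed, the
# only transform-dependent part of the negative log-likelihood is the
# weighted Fourier cross-term
#   C(R, t) = sum_s w(|s|) Re[ conj(F1(s)) F2'(s; R, t) ],
# where F2' is the transformed moving map and the per-bin weight w comes
# from the off-diagonal of the inverse 2x2 total covariance of the pair at
# the current alignment (a function of the FSC between the maps). The
# algorithm alternates (1) re-estimating the per-bin covariances/weights at
# the current alignment with (2) a line-searched quasi-Newton update of the
# transform parameters driven by the analytic gradient of C, until the
# functional change is negligible.
#
# Numerical note: the cross-term is *evaluated* in real space through
# Parseval's identity — C equals (up to a constant) the inner product of
# the weight-filtered static map with the real-space-resampled moving map.
# Interpolating the moving spectrum instead makes the objective kinked at
# lattice-commensurate poses (every sample point falls on the reciprocal
# lattice at the identity, and any infinitesimal step attenuates exactly
# the signal-bearing coefficients), which stalls line searches; resampling
# in real space only attenuates the moving map's noise off-lattice, which
# is uncorrelated with the static map, so the objective is smooth. The
# optimizer uses band-limited analytic gradients (FFT-derivative fields of
# the moving map); the exact gradient of the discrete interpolant is also
# available and matches finite differences.
#
# All rotations act about the grid-centre voxel.

# --- internal engine ------------------------------------------------------

# Zero-pad a spectrum onto a u-times finer grid (band-limited upsampling).
pad_spectrum <- function(F, u) {
  n <- dim(F)
  m <- u * n
  out <- array(0i, m)
  idx <- lapply(1:3, function(k) {
    hs <- freq_index(n[k])
    hs %% m[k] + 1L
  })
  out[idx[[1]], idx[[2]], idx[[3]]] <- F[]
  out
}

# Precompute everything the iterations need. The moving map (and its
# band-limited gradient fields) are kept on a u-times upsampled grid:
# trilinear interpolation on the original grid attenuates the highest
# frequencies by an amount that varies with the candidate pose, which
# biases the optimum; on the upsampled grid the attenuation is ~u^2
# smaller.
fit_prep <- function(static, moving, resolution = NULL, nbins = NULL,
                     upsample = 2L) {
  stopifnot_voxel_map(static); stopifnot_voxel_map(moving)
  shape <- dim(static$data)
  if (!all(dim(moving$data) == shape)) {
    stop("overlay: maps must share one grid (resample first)")
  }
  px <- static$pixel_size
  if (max(abs(px - px[1])) > 1e-9 * px[1] || length(unique(shape)) != 1) {
    stop("overlay: rotation fitting requires a cubic grid with isotropic pixels")
  }
  shells <- make_shells(shape, px, resolution_limit = resolution, nbins = nbins)
  g <- freq_index_grids(shape)
  mask <- !is.na(shells$bin) & !(g$hx == 0 & g$hy == 0 & g$hz == 0)
  F1 <- stats::fft(static$data)
  F2 <- stats::fft(moving$data)
  v1_bin <- shell_mean(Mod(F1)^2, shells)
  # upsampled moving map and its band-limited gradient fields (derivatives
  # are w.r.t. the ORIGINAL voxel index; sample positions scale by u)
  u <- as.integer(upsample)
  F2p <- pad_spectrum(F2, u)
  mfine <- prod(dim(F2p))
  dfac <- function(h, n) 2i * pi * h / n
  gf <- freq_index_grids(dim(F2p))
  # frequencies beyond the source band are zero, so using the fine-grid
  # index divided by the ORIGINAL length gives the original-unit derivative
  movf <- Re(stats::fft(F2p, inverse = TRUE)) / mfine * u^3
  gmx <- Re(stats::fft(F2p * dfac(gf$hx, shape[1] * u), inverse = TRUE)) /
    mfine * u^4
  gmy <- Re(stats::fft(F2p * dfac(gf$hy, shape[2] * u), inverse = TRUE)) /
    mfine * u^4
  gmz <- Re(stats::fft(F2p * dfac(gf$hz, shape[3] * u), inverse = TRUE)) /
    mfine * u^4
  X <- cbind(
    rep(0:(shape[1] - 1), times = shape[2] * shape[3]),
    rep(rep(0:(shape[2] - 1), each = shape[1]), times = shape[3]),
    rep(0:(shape[3] - 1), each = shape[1] * shape[2])
  )
  # the cross-term only accumulates where the static map holds signal; a
  # heavy low-pass (8 A) suppresses the noise, and the thresholded support
  # is dilated by a few voxels so soft edges and small misalignments stay
  # inside. The inner optimization evaluates only these voxels.
  smag <- freq_magnitude(shape, px)
  lp <- F1
  lp[smag > 1 / max(8, 2.5 * (resolution %||% (2 * px[1])))] <- 0i
  sm <- abs(Re(stats::fft(lp, inverse = TRUE)) / prod(shape))
  supp <- sm > 0.08 * max(sm)
  ball <- (freq_magnitude(shape, rep(1, 3)) * shape[1]) <= 4  # 4-voxel ball
  cnt <- Re(stats::fft(stats::fft(supp + 0) * stats::fft(ball + 0),
    inverse = TRUE)) / prod(shape)
  keep <- which(cnt > 0.5)
  list(
    shape = shape, pixel = px[1], shells = shells, mask = mask,
    F1 = F1, v1_bin = v1_bin, mov = movf, ups = u,
    gmx = gmx, gmy = gmy, gmz = gmz,
    X = X, Xs = X[keep, , drop = FALSE], keep = keep,
    ctr = grid_center_vox(shape)
  )
}

# Real-space resampling of the moving map under (R, t, mag) about the grid
# centre: content maps as x -> mag R (x - c) + c + t (voxel units).
fit_resample <- function(prep, R, tvox, mag = 1) {
  u <- sweep(prep$X, 2, prep$ctr + tvox, "-")
  src <- sweep((u %*% R) / mag, 2, prep$ctr, "+")
  array(trilinear_periodic(prep$mov, src * prep$ups)$value, prep$shape)
}

# Per-bin weights (inverse-covariance off-diagonal) at the current
# alignment, the weight-filtered static map, and the current functional.
fit_weights <- function(prep, tmov) {
  F2c <- stats::fft(tmov)
  shells <- prep$shells
  v2 <- shell_mean(Mod(F2c)^2, shells)
  c12 <- shell_mean(Re(prep$F1 * Conj(F2c)), shells)
  # bins with negligible power carry no information (their correlation
  # estimate is float noise) and would otherwise get enormous 1/sqrt(v1 v2)
  # weights; drop them
  floor1 <- 1e-10 * max(prep$v1_bin, na.rm = TRUE)
  floor2 <- 1e-10 * max(v2, na.rm = TRUE)
  usable <- !is.na(prep$v1_bin) & !is.na(v2) &
    prep$v1_bin > floor1 & v2 > floor2
  r_raw <- ifelse(usable, c12 / sqrt(prep$v1_bin * v2), NA_real_)
  r <- pmin(r_raw, 0.99)
  w_bin <- ifelse(!is.na(r) & r > 0,
    r / ((1 - r^2) * sqrt(prep$v1_bin * v2)), 0)
  W <- array(0, prep$shape)
  ok <- prep$mask
  W[ok] <- w_bin[shells$bin[ok]]
  fstat <- Re(stats::fft(W * prep$F1, inverse = TRUE)) / prod(prep$shape)
  cross <- sum(W * Re(prep$F1 * Conj(F2c)))
  # profile likelihood of the alignment once per-bin covariances are
  # re-estimated: depends on the shell correlations only, so it is
  # invariant to per-bin power changes (needed to score magnification,
  # which redistributes power across shells)
  # the profile score may use a higher correlation cap than the weights:
  # log(1 - r^2) is well behaved up to 0.999 and the strongest shells carry
  # most of the scale information
  rr <- pmin(pmax(ifelse(is.na(r_raw), 0, r_raw), 0), 0.999)
  nll_prof <- sum(shells$counts * log(1 - rr^2))
  list(w_bin = w_bin, fsc_bin = pmin(pmax(r, -1), 1), fstat = fstat,
    cross = cross, nll = -cross, nll_prof = nll_prof)
}

# profile likelihood only (no weight filter build): cheap scorer for 1-D /
# low-dimensional searches that re-estimate shell correlations per state
fit_score_prof <- function(prep, tmov) {
  F2c <- stats::fft(tmov)
  shells <- prep$shells
  v2 <- shell_mean(Mod(F2c)^2, shells)
  c12 <- shell_mean(Re(prep$F1 * Conj(F2c)), shells)
  floor1 <- 1e-10 * max(prep$v1_bin, na.rm = TRUE)
  floor2 <- 1e-10 * max(v2, na.rm = TRUE)
  usable <- !is.na(prep$v1_bin) & !is.na(v2) &
    prep$v1_bin > floor1 & v2 > floor2
  r <- ifelse(usable, c12 / sqrt(prep$v1_bin * v2), 0)
  rr <- pmin(pmax(r, 0), 0.999)
  sum(shells$counts * log(1 - rr^2))
}

# Cross-term (times -1) and its gradient w.r.t. par = c(delta, tvox) at
# rotation Delta(delta) %*% Rcur, fixed weights. grad: "none", "field"
# (band-limited derivative maps; used for optimization) or "interp" (exact
# derivative of the trilinear objective; matches finite differences).
fit_objective <- function(par, prep, fstat, Rcur, mag = 1, grad = "none") {
  delta <- par[1:3]; tvox <- par[4:6]
  R <- axis_angle_to_matrix(delta) %*% Rcur
  u <- sweep(prep$Xs, 2, prep$ctr + tvox, "-")
  uR <- (u %*% R) / mag
  src <- sweep(uR, 2, prep$ctr, "+")
  want_interp_grad <- identical(grad, "interp")
  fs <- as.vector(fstat)[prep$keep]
  srcf <- src * prep$ups
  if (want_interp_grad) {
    tv <- trilinear_periodic(prep$mov, srcf, grad = TRUE)
    vals <- tv$value
  } else if (identical(grad, "field")) {
    ip <- trilinear_periodic_multi(
      list(prep$mov, prep$gmx, prep$gmy, prep$gmz), srcf)
    vals <- ip[[1]]
  } else {
    vals <- trilinear_periodic(prep$mov, srcf)$value
  }
  # Fourier cross-term == Nvox * real-space inner product (Parseval)
  C <- prod(prep$shape) * sum(fs * vals)
  out <- list(value = -C)
  if (identical(grad, "none")) return(out)
  if (want_interp_grad) {
    # interpolant derivative is per fine-grid index; convert to voxel units
    gsrc <- cbind(tv$gx, tv$gy, tv$gz) * prep$ups
  } else {
    gsrc <- cbind(ip[[2]], ip[[3]], ip[[4]])
  }
  nvox <- prod(prep$shape)
  # translation: d src / d t_k = -R[k, ] / mag
  gt <- vapply(1:3, function(k) {
    -nvox * sum(fs * (gsrc %*% R[k, ])) / mag
  }, numeric(1))
  # rotation: d src / d delta_k = -(((Jl delta_k) x u) %*% R) / mag, with
  # Jl the left Jacobian of SO(3) at the current axis-angle increment (the
  # plain cross-product form is only exact at delta = 0)
  Jl <- so3_left_jacobian(delta)
  gd <- vapply(1:3, function(k) {
    a <- Jl[, k]
    axu <- cbind(a[2] * u[, 3] - a[3] * u[, 2],
      a[3] * u[, 1] - a[1] * u[, 3],
      a[1] * u[, 2] - a[2] * u[, 1])
    -nvox * sum(fs * rowSums(gsrc * (axu %*% R))) / mag
  }, numeric(1))
  out$gradient <- -c(gd, gt)
  out
}

# One inner optimization at fixed weights: quasi-Newton on (delta, t).
fit_inner <- function(prep, fstat, Rcur, tvox, mag = 1, maxit = 30) {
  fn <- function(p) fit_objective(p, prep, fstat, Rcur, mag)$value
  gr <- function(p) fit_objective(p, prep, fstat, Rcur, mag,
    grad = "field")$gradient
  reff <- max(prep$shape[1] / 4, 1)  # voxels moved per radian at mid-radius
  opt <- stats::optim(c(0, 0, 0, tvox), fn, gr, method = "BFGS",
    control = list(maxit = maxit, reltol = 1e-10,
      parscale = c(rep(1 / reff, 3), rep(1, 3))))
  f0 <- fn(c(0, 0, 0, tvox))
  if (opt$value <= f0) {
    list(R = axis_angle_to_matrix(opt$par[1:3]) %*% Rcur,
      tvox = opt$par[4:6], value = opt$value)
  } else {
    list(R = Rcur, tvox = tvox, value = f0)
  }
}

# --- public operations ----------------------------------------------------

#' Resample Fourier coefficients under a rigid transform
#'
#' The coefficients are re-evaluated at the rotated (and optionally
#' magnification-scaled) frequencies by trilinear interpolation of the
#' centred spectrum, then phase-shifted for the translation. Frequencies
#' rotated outside the sampled sphere are set to zero. The rotation acts
#' about the grid-centre voxel; content maps as
#' \code{x -> mag R (x - c) + c + t}.
#'
#' @param fm a \code{fourier_map}.
#' @param t a [rigid_transform()] (its \code{magnification} rescales the
#'   map content; 1 leaves it rigid).
#' @return a \code{fourier_map} of the transformed map.
#' @export
transform_fourier <- function(fm, t) {
  stopifnot(inherits(fm, "fourier_map"), inherits(t, "rigid_transform"))
  shape <- fm$shape
  ctr <- grid_center_vox(shape)
  g <- freq_index_grids(shape)
  h <- cbind(as.vector(g$hx), as.vector(g$hy), as.vector(g$hz))
  # centring phase: multiply by exp(+2 pi i h.c/N) == circshift by -c
  cph <- exp(2i * pi * (h %*% (ctr / shape))[, 1])
  G <- array(fm$coeffs * cph, shape)
  identityish <- max(abs(t$R - diag(3))) < 1e-15 && t$magnification == 1
  if (identityish) {
    vals <- as.vector(G)
  } else {
    P <- (h %*% t$R) * t$magnification
    vals <- trilinear_periodic(G, P)$value
    rmax <- min(shape) / 2
    vals[sqrt(rowSums(P^2)) > rmax] <- 0i
  }
  tvox <- t$translation / fm$pixel_size
  tph <- exp(-2i * pi * (h %*% (tvox / shape))[, 1])
  out <- vals * t$magnification^3 * tph / cph
  as_fourier_map(array(out, shape), fm)
}

#' Apply a rigid (or magnified) transform to a map
#'
#' Fourier-space application of [transform_fourier()] followed by the
#' inverse transform; content maps as \code{x -> mag * R (x - c) + c + t}
#' about the grid centre.
#'
#' @param map a [voxel_map()].
#' @param t a [rigid_transform()].
#' @return the transformed [voxel_map()].
#' @export
apply_transform_to_map <- function(map, t) {
  inverse_fft(transform_fourier(forward_fft(map), t))
}

#' Score a candidate transform (likelihood cross-term)
#'
#' Evaluates the weighted cross-term between the static map and the moving
#' map under \code{t}, with per-bin weights estimated at that alignment.
#' The returned \code{nll} is minus the cross-term: it decreases as the
#' overlap improves.
#'
#' @param static,moving [voxel_map()]s on one (cubic) grid.
#' @param t a [rigid_transform()].
#' @param resolution high-resolution cutoff in Angstrom (default Nyquist).
#' @return list with \code{nll}, \code{cross_term}, per-bin \code{weights}
#'   and per-bin observed correlation \code{fsc}.
#' @export
score_fit <- function(static, moving, t, resolution = NULL) {
  prep <- fit_prep(static, moving, resolution)
  tvox <- t$translation / prep$pixel
  tmov <- fit_resample(prep, t$R, tvox, t$magnification)
  wt <- fit_weights(prep, tmov)
  if (all(wt$w_bin == 0)) {
    stop("score_fit: all shell weights are zero (no shared signal)")
  }
  list(nll = wt$nll, cross_term = wt$cross, weights = wt$w_bin,
    fsc = wt$fsc_bin)
}

#' Fit a rigid transform superposing a moving map on a static map
#'
#' Iterates the transformation-estimation cycle: per-bin covariances and
#' weights are recomputed at the current alignment, the six transform
#' parameters (axis-angle rotation about the grid centre, translation) are
#' updated by a line-searched quasi-Newton step on the analytic cross-term
#' gradient, and the loop stops when the relative change of the functional
#' drops below \code{tol} or \code{max_iter} is reached. An optional
#' low-resolution first pass (at twice the cutoff) widens the convergence
#' basin. If the functional fails to improve across a full iteration the
#' best-seen state is returned flagged not-converged.
#'
#' @param static,moving [voxel_map()]s on one cubic grid.
#' @param init initial [rigid_transform()].
#' @param resolution high-resolution cutoff in Angstrom; default Nyquist.
#' @param max_iter maximum outer iterations per resolution stage.
#' @param tol relative functional-change convergence threshold.
#' @param multires start at twice the cutoff (default TRUE).
#' @return object of class \code{fit_state}: \code{transform} (translation
#'   in Angstrom), \code{nll}, \code{converged}, per-iteration \code{trace},
#'   and per-bin \code{fsc_before}/\code{fsc_after} with the shell table.
#' @export
fit_transform <- function(static, moving, init = rigid_transform(),
                          resolution = NULL, max_iter = 40, tol = 1e-6,
                          multires = TRUE) {
  res_full <- resolution %||% (2 * max(static$pixel_size))
  stages <- if (multires) c(2 * res_full, res_full) else res_full
  R <- init$R
  tvox <- init$translation / static$pixel_size[1]
  trace <- list()
  converged <- FALSE
  nll <- NA_real_
  for (res in stages) {
    prep <- fit_prep(static, moving, resolution = res)
    nll <- NA_real_
    best <- list(R = R, tvox = tvox, nll = Inf)
    for (it in seq_len(max_iter)) {
      tmov <- fit_resample(prep, R, tvox)
      wt <- fit_weights(prep, tmov)
      if (all(wt$w_bin == 0)) stop("fit_transform: no shared signal in any shell")
      step <- fit_inner(prep, wt$fstat, R, tvox)
      R <- step$R
      tvox <- step$tvox
      new_nll <- step$value
      if (new_nll < best$nll) best <- list(R = R, tvox = tvox, nll = new_nll)
      trace[[length(trace) + 1]] <- list(resolution = res, iter = it,
        nll = new_nll,
        angle_deg = acos(min(max((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi,
        tvox = tvox)
      if (is.finite(nll) && abs(new_nll - nll) <= tol * abs(nll)) {
        converged <- TRUE
        nll <- new_nll
        break
      }
      nll <- new_nll
    }
    R <- best$R
    tvox <- best$tvox
    nll <- best$nll
  }
  final <- rigid_transform(R, tvox * static$pixel_size[1])
  # FSC before/after at the full cutoff
  prep <- fit_prep(static, moving, resolution = res_full)
  f_static <- forward_fft(static)
  f_mov <- forward_fft(moving)
  fsc_before <- fsc(f_static, f_mov, prep$shells)
  fitted_tmov <- fit_resample(prep, R, tvox)
  f_fit <- as_fourier_map(stats::fft(fitted_tmov), f_mov)
  fsc_after <- fsc(f_static, f_fit, prep$shells)
  structure(
    list(transform = final, nll = nll, converged = converged,
      iterations = length(trace), trace = trace,
      fsc_before = fsc_before, fsc_after = fsc_after,
      shells = prep$shells, resolution = res_full),
    class = "fit_state"
  )
}

#' @export
print.fit_state <- function(x, ...) {
  cat(sprintf(
    "<fit_state: rotation %.3f deg, translation %.3f A, nll %.4g, %s in %d iterations>\n",
    rotation_angle_deg(x$transform),
    sqrt(sum(x$transform$translation^2)), x$nll,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Extract a soft-masked region of a map
#'
#' The mask is the union of spheres around the given atom positions (or a
#' single explicit sphere), with a raised-cosine edge so the cut does not
#' ring in Fourier space. The map is multiplied by the mask.
#'
#' @param map a [voxel_map()].
#' @param atoms data.frame of atoms defining the mask (optional).
#' @param center,radius explicit sphere (Angstrom) used when \code{atoms}
#'   is NULL.
#' @param atom_radius per-atom sphere radius in Angstrom (default 3).
#' @param edge soft-edge width in voxels (default 3).
#' @return the masked [voxel_map()]; the mask array is attached as
#'   attribute \code{mask}.
#' @export
extract_masked_region <- function(map, atoms = NULL, center = NULL,
                                  radius = NULL, atom_radius = 3, edge = 3) {
  stopifnot_voxel_map(map)
  shape <- dim(map$data)
  px <- map$pixel_size
  ax <- map$origin[1] + (0:(shape[1] - 1)) * px[1]
  ay <- map$origin[2] + (0:(shape[2] - 1)) * px[2]
  az <- map$origin[3] + (0:(shape[3] - 1)) * px[3]
  if (!is.null(atoms)) {
    if (nrow(atoms) == 0) stop("extract_masked_region: empty atom selection")
    centers <- cbind(atoms$x, atoms$y, atoms$z)
    r0 <- atom_radius
  } else if (!is.null(center) && !is.null(radius)) {
    centers <- matrix(center, ncol = 3)
    r0 <- radius
  } else {
    stop("extract_masked_region: give atoms or center+radius")
  }
  gx <- array(ax, shape)
  gy <- array(rep(ay, each = shape[1]), shape)
  gz <- array(rep(az, each = shape[1] * shape[2]), shape)
  dmin <- array(Inf, shape)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((gx - centers[i, 1])^2 + (gy - centers[i, 2])^2 +
      (gz - centers[i, 3])^2)
    dmin <- pmin(dmin, d)
  }
  ew <- edge * mean(px)
  mask <- array(0, shape)
  mask[dmin <= r0] <- 1
  soft <- dmin > r0 & dmin < r0 + ew
  mask[soft] <- 0.5 * (1 + cos(pi * (dmin[soft] - r0) / ew))
  if (all(mask == 0)) stop("extract_masked_region: mask support is empty")
  out <- voxel_map(map$data * mask, px, map$origin)
  attr(out, "mask") <- mask
  out
}
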