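# Synthetic voxel phantoms and ground-truth generators.
#
# Gaussian-blob phantoms stand in for reconstructed density; half-map pairs
# are emulated as phantom + independent white Gaussian noise; transformed
# and magnified copies are produced by a real-space trilinear resampler -
# deliberately a different code path from the Fourier-space machinery the
# fits use, so parameter-recovery tests are not self-confirming.

#' Specify a Gaussian-blob phantom
#'
#' @param shape grid dimensions (length 3 or scalar for a cube).
#' @param pixel_size pixel size in Angstrom.
#' @param blobs data.frame with columns \code{x,y,z} (centres in Angstrom),
#'   \code{width} (Gaussian sigma in Angstrom) and \code{amplitude}.
#' @param seed integer seed recorded with the spec (generators are
#'   deterministic given the spec).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape, pixel_size = 1, blobs, seed = 1L) {
  shape <- rep_len(as.integer(shape), 3L)
  pixel_size <- rep_len(as.numeric(pixel_size), 3L)
  stopifnot(all(c("x", "y", "z", "width", "amplitude") %in% names(blobs)))
  if (any(blobs$width <= 0)) stop("phantom_spec: blob widths must be positive")
  ext <- shape * pixel_size
  inside <- blobs$x >= 0 & blobs$x <= ext[1] & blobs$y >= 0 &
    blobs$y <= ext[2] & blobs$z >= 0 & blobs$z <= ext[3]
  if (!all(inside)) stop("phantom_spec: blob centres outside the grid")
  structure(list(shape = shape, pixel_size = pixel_size, blobs = blobs,
    seed = as.integer(seed)), class = "phantom_spec")
}

#' A default multi-blob phantom spec
#'
#' A reproducible, markedly asymmetric cluster of blobs around the grid
#' centre. The defaults (16 blobs, widths 1.5-2.8 pixels) give the map
#' enough high-frequency structure that an orientation is well determined
#' - a handful of broad blobs would be unrealistically smooth compared
#' with protein density - while staying well inside the box so periodic
#' operations do not wrap content.
#'
#' @param shape grid dimensions (default 48).
#' @param pixel_size pixel size in Angstrom (default 1).
#' @param n_blobs number of blobs.
#' @param seed RNG seed used to draw blob positions/widths/amplitudes.
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(shape = 48, pixel_size = 1, n_blobs = 16,
                                seed = 1L) {
  shape <- rep_len(as.integer(shape), 3L)
  pixel_size <- rep_len(as.numeric(pixel_size), 3L)
  ext <- shape * pixel_size
  set.seed(seed)
  ctr <- ext / 2
  spread <- ext / 7
  blobs <- data.frame(
    x = stats::rnorm(n_blobs, ctr[1], spread[1]),
    y = stats::rnorm(n_blobs, ctr[2], spread[2]),
    z = stats::rnorm(n_blobs, ctr[3], spread[3]),
    width = stats::runif(n_blobs, 1.5, 2.8) * mean(pixel_size),
    amplitude = stats::runif(n_blobs, 0.6, 1.4)
  )
  # keep centres well inside the box
  for (k in 1:3) {
    col <- c("x", "y", "z")[k]
    blobs[[col]] <- pmin(pmax(blobs[[col]], 0.22 * ext[k]), 0.78 * ext[k])
  }
  phantom_spec(shape, pixel_size, blobs, seed)
}

#' Realize a phantom map from its spec
#'
#' Sum of isotropic 3D Gaussians \code{a exp(-r^2 / (2 w^2))} evaluated at
#' voxel centres. Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return a [voxel_map()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; px <- spec$pixel_size
  ax <- (0:(shape[1] - 1)) * px[1]
  ay <- (0:(shape[2] - 1)) * px[2]
  az <- (0:(shape[3] - 1)) * px[3]
  a <- array(0, shape)
  for (i in seq_len(nrow(spec$blobs))) {
    b <- spec$blobs[i, ]
    gx <- exp(-(ax - b$x)^2 / (2 * b$width^2))
    gy <- exp(-(ay - b$y)^2 / (2 * b$width^2))
    gz <- exp(-(az - b$z)^2 / (2 * b$width^2))
    a <- a + b$amplitude * (gx %o% gy %o% gz)
  }
  voxel_map(a, px)
}

#' Noise level giving a target signal-to-noise ratio
#'
#' SNR is defined globally as the ratio of the map's variance (about its
#' mean) to the white-noise variance added per half map.
#'
#' @param map a [voxel_map()].
#' @param snr target signal-to-noise ratio.
#' @return the white-noise standard deviation.
#' @export
noise_sigma_for_snr <- function(map, snr) {
  stopifnot(snr > 0)
  sqrt(stats::var(as.vector(map$data)) / snr)
}

#' Emulate a pair of half maps
#'
#' Halves are the input map plus independent white Gaussian noise of the
#' given standard deviation. The ground-truth record carries the noise SD
#' and the per-bin signal power of the clean map, so shell estimators can
#' be checked against the generator.
#'
#' @param map the clean [voxel_map()].
#' @param noise_sigma white-noise SD per half (>= 0).
#' @param seed integer seed.
#' @param shells optional [make_shells()] used for the per-bin truth
#'   record.
#' @return list(\code{half1}, \code{half2}, \code{truth}) where truth has
#'   \code{noise_sigma}, \code{noise_power_per_coeff} and (if shells were
#'   given) per-bin \code{signal_power}.
#' @export
make_half_pair <- function(map, noise_sigma, seed = 1L, shells = NULL) {
  stopifnot_voxel_map(map)
  if (noise_sigma < 0) stop("make_half_pair: noise_sigma must be >= 0")
  shape <- dim(map$data)
  set.seed(seed)
  n1 <- array(stats::rnorm(prod(shape), 0, noise_sigma), shape)
  n2 <- array(stats::rnorm(prod(shape), 0, noise_sigma), shape)
  truth <- list(
    noise_sigma = noise_sigma,
    # white real-space noise of variance v has flat Fourier power Nvox * v
    noise_power_per_coeff = prod(shape) * noise_sigma^2
  )
  if (!is.null(shells)) {
    Fm <- forward_fft(map)
    truth$signal_power <- shell_mean(Mod(Fm$coeffs)^2, shells)
  }
  list(
    half1 = voxel_map(map$data + n1, map$pixel_size, map$origin),
    half2 = voxel_map(map$data + n2, map$pixel_size, map$origin),
    truth = truth
  )
}

#' Transformed/magnified copy of a map (independent resampler)
#'
#' Real-space trilinear resampling under \code{x -> mag R (x - c) + c + t}
#' about the grid centre, with periodic wrapping. This is the ground-truth
#' generator for transform-recovery tests and shares no code with the
#' Fourier-space transform used by the fits.
#'
#' @param map a [voxel_map()].
#' @param t a [rigid_transform()] (its \code{magnification} field scales
#'   the content).
#' @param upsample band-limited (Fourier zero-pad) upsampling factor
#'   applied before the trilinear gather; 2 by default, keeping the
#'   resampler's interpolation smoothing small. Set 1 for plain
#'   single-grid trilinear.
#' @return the transformed [voxel_map()].
#' @export
make_transformed_copy <- function(map, t, upsample = 2L) {
  stopifnot_voxel_map(map)
  stopifnot(inherits(t, "rigid_transform"))
  identityish <- max(abs(t$R - diag(3))) < 1e-15 &&
    all(t$translation == 0) && t$magnification == 1
  if (identityish) return(map)
  shape <- dim(map$data)
  px <- map$pixel_size
  ctr <- map$origin + grid_center_vox(shape) * px
  ax <- map$origin[1] + (0:(shape[1] - 1)) * px[1]
  ay <- map$origin[2] + (0:(shape[2] - 1)) * px[2]
  az <- map$origin[3] + (0:(shape[3] - 1)) * px[3]
  pts <- cbind(
    rep(ax, times = shape[2] * shape[3]),
    rep(rep(ay, each = shape[1]), times = shape[3]),
    rep(az, each = shape[1] * shape[2])
  )
  # source position for each output voxel: invert the forward mapping
  rel <- sweep(pts, 2, ctr + t$translation, "-")
  src <- (rel %*% t$R) / t$magnification   # rows times R == R^-1 applied
  src <- sweep(src, 2, ctr, "+")
  idx <- sweep(sweep(src, 2, map$origin, "-"), 2, px, "/")
  u <- as.integer(upsample)
  if (u > 1L) {
    fine <- Re(stats::fft(pad_spectrum(stats::fft(map$data), u),
      inverse = TRUE)) / prod(shape)
    v <- trilinear_periodic(fine, idx * u)$value
  } else {
    v <- trilinear_periodic(map$data, idx)$value
  }
  voxel_map(array(v, shape), px, map$origin)
}

#' Pseudo-atom model reproducing a phantom
#'
#' One atom per blob, placed at the blob centre, with occupancy 1 and the
#' B value chosen so the Gaussian-atom density model reproduces the blob
#' width: a blob of sigma w matches b = B + base_width = 8 pi^2 w^2, and
#' the amplitude is scaled so peak heights agree.
#'
#' @param spec a [phantom_spec()].
#' @param base_width the base width that will be passed to
#'   [model_to_map()] (default 10).
#' @return list(\code{atoms} data.frame, \code{amplitudes} named vector to
#'   pass to [model_to_map()]).
#' @export
make_model_for_phantom <- function(spec, base_width = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  b <- 8 * pi^2 * spec$blobs$width^2
  if (any(b <= base_width)) {
    stop("make_model_for_phantom: blob width too small for the base width")
  }
  # model_to_map peak density is occ * amp * (4 pi / b)^{3/2} / Vpix-free
  # units; match amp so the real-space peak equals the blob amplitude
  amp <- spec$blobs$amplitude / (4 * pi / b)^1.5
  atoms <- empty_atoms()[0, ]
  atoms <- data.frame(
    x = spec$blobs$x, y = spec$blobs$y, z = spec$blobs$z,
    occ = 1, b = b - base_width,
    element = sprintf("X%d", seq_len(nrow(spec$blobs))),
    resname = "BLB", resno = seq_len(nrow(spec$blobs)), chain = "A",
    name = "X", stringsAsFactors = FALSE
  )
  amplitudes <- stats::setNames(amp, toupper(atoms$element))
  list(atoms = atoms, amplitudes = amplitudes)
}
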