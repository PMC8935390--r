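# Fourier transforms of voxel maps.
#
# Convention: unnormalized forward transform F(s) = sum_x f(x) e^{-2 pi i s.x}
# (base R fft), normalized inverse (divide by the voxel count). Under this
# convention Parseval reads sum |f|^2 = (1/Nvox) sum |F|^2.

#' Forward FFT of a VoxelMap
#'
#' @param map a [voxel_map()].
#' @return object of class \code{fourier_map}: complex coefficient array
#'   (\code{coeffs}), grid \code{shape}, \code{pixel_size}, and the source
#'   map's \code{origin}.
#' @export
forward_fft <- function(map) {
  stopifnot_voxel_map(map)
  structure(
    list(
      coeffs = stats::fft(map$data),
      shape = dim(map$data),
      pixel_size = map$pixel_size,
      origin = map$origin
    ),
    class = "fourier_map"
  )
}

#' Inverse FFT back to a VoxelMap
#'
#' @param fm a \code{fourier_map}.
#' @param real take the real part (valid when the coefficients are
#'   Hermitian); default TRUE.
#' @return a [voxel_map()].
#' @export
inverse_fft <- function(fm, real = TRUE) {
  stopifnot(inherits(fm, "fourier_map"))
  a <- stats::fft(fm$coeffs, inverse = TRUE) / prod(fm$shape)
  if (real) a <- Re(a)
  voxel_map(a, pixel_size = fm$pixel_size, origin = fm$origin)
}

#' @export
print.fourier_map <- function(x, ...) {
  cat(sprintf("<fourier_map %dx%dx%d, pixel %.4g A>\n",
    x$shape[1], x$shape[2], x$shape[3], x$pixel_size[1]))
  invisible(x)
}

as_fourier_map <- function(coeffs, like) {
  structure(
    list(coeffs = coeffs, shape = like$shape, pixel_size = like$pixel_size,
      origin = like$origin),
    class = "fourier_map"
  )
}
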