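#' Construct a VoxelMap
#'
#' A \code{VoxelMap} is the package's real-space density container: a 3D
#' array of density values together with the grid geometry (pixel size per
#' axis, cell edges, origin in Angstrom). Voxel \code{(0,0,0)} (0-based) is
#' centred at the map origin, so the Angstrom position of voxel index
#' \code{(i,j,k)} is \code{origin + c(i,j,k) * pixel_size}.
#'
#' @param data numeric 3D array of density values.
#' @param pixel_size voxel edge length(s) in Angstrom; scalar or length 3.
#' @param origin map origin in Angstrom (length 3).
#' @return object of class \code{voxel_map} with fields \code{data},
#'   \code{pixel_size}, \code{cell} (grid extent in Angstrom) and
#'   \code{origin}.
#' @examples
#' vm <- voxel_map(array(rnorm(8^3), c(8, 8, 8)), pixel_size = 1.1)
#' dim(vm$data)
#' @export
voxel_map <- function(data, pixel_size = 1, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("voxel_map: 'data' must be a 3D array")
  pixel_size <- rep_len(as.numeric(pixel_size), 3L)
  if (any(pixel_size <= 0)) stop("voxel_map: pixel_size must be positive")
  if (any(!is.finite(data))) stop("voxel_map: data contains NaN/Inf values")
  structure(
    list(
      data = data,
      pixel_size = pixel_size,
      cell = dim(data) * pixel_size,
      origin = rep_len(as.numeric(origin), 3L)
    ),
    class = "voxel_map"
  )
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf(
    "<voxel_map %dx%dx%d, pixel %.4g/%.4g/%.4g A, origin (%.3g, %.3g, %.3g) A>\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$pixel_size[1], x$pixel_size[2], x$pixel_size[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' @export
dim.voxel_map <- function(x) dim(x$data)

# shared validation used by I/O and generators
stopifnot_voxel_map <- function(m) {
  if (!inherits(m, "voxel_map")) stop("expected a 'voxel_map' object")
  invisible(m)
}

# Angstrom position -> 0-based fractional voxel index
pos_to_index <- function(map, pos) {
  pos <- matrix(pos, ncol = 3)
  sweep(sweep(pos, 2, map$origin, "-"), 2, map$pixel_size, "/")
}
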