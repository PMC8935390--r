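# MRC2014 map input/output.
#
# The format is a fixed 1024-byte header (56 4-byte words plus ten 80-byte
# labels) followed by the voxel block. Only the header words needed for
# single-particle work are interpreted: grid size, mode, axis order
# (MAPC/MAPR/MAPS), sampling (MX/MY/MZ), cell, origin, and the machine
# stamp. Maps are written in mode 2 (float32), little-endian.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 density map
#'
#' Reads a density map, promotes integer voxel modes to double, permutes the
#' data block so the returned array is ordered (x, y, z) regardless of the
#' file's MAPC/MAPR/MAPS setting, and validates the voxel block. If the
#' header cell is inconsistent with the grid sampling the cell is recomputed
#' from the pixel size with a warning.
#'
#' @param path path to an MRC file.
#' @return a [voxel_map()].
#' @details The ORIGIN header record (words 50-52) is used as the map
#'   origin. If it is zero but NXSTART/NYSTART/NZSTART are set, the start
#'   indices are converted to Angstrom; if both are present and disagree the
#'   ORIGIN record wins and a message is emitted.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("read_map: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_raw <- readBin(con, "raw", MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES) stop("read_map: truncated header")
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "integer",
    1, size = 4, endian = endian)
  num_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "numeric",
    1, size = 4, endian = endian)

  # machine stamp sanity (word 54, bytes 213-216): 0x44 => little-endian
  machst <- hdr_raw[213:216]
  if (!(as.integer(machst[1]) %in% c(0x44, 0x00))) {
    stop("read_map: unsupported machine stamp (big-endian file?)")
  }
  if (rawToChar(hdr_raw[209:211]) != "MAP") {
    stop("read_map: malformed header: MAP identifier missing (word 53)")
  }

  nc <- int_at(1); nr <- int_at(2); ns <- int_at(3)
  if (any(c(nc, nr, ns) <= 0) || any(c(nc, nr, ns) > 4096)) {
    stop("read_map: malformed header: bad grid size NX/NY/NZ")
  }
  mode <- int_at(4)
  nstart <- c(int_at(5), int_at(6), int_at(7))
  mgrid <- c(int_at(8), int_at(9), int_at(10))
  cella <- c(num_at(11), num_at(12), num_at(13))
  cellb <- c(num_at(14), num_at(15), num_at(16))
  mapcrs <- c(int_at(17), int_at(18), int_at(19))
  origin <- c(num_at(50), num_at(51), num_at(52))

  if (any(abs(cellb - 90) > 1e-3)) {
    stop("read_map: non-orthogonal cell (angles != 90 deg) not supported")
  }
  if (!all(sort(mapcrs) == 1:3)) {
    stop("read_map: malformed header: MAPC/MAPR/MAPS must be a permutation of 1:3")
  }

  nvox <- as.numeric(nc) * nr * ns
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE,
      endian = endian)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = TRUE,
      endian = endian)),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = endian),
    "6" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = FALSE,
      endian = endian)),
    stop("read_map: unsupported MRC mode ", mode)
  )
  if (length(data) < nvox) stop("read_map: truncated data block")
  if (any(!is.finite(data))) stop("read_map: map contains NaN/Inf voxels")
  a <- array(data, dim = c(nc, nr, ns))

  # file axes (columns, rows, sections) -> logical (x, y, z)
  # mapcrs[k] says which of x/y/z runs along file axis k.
  perm <- order(mapcrs)     # position of x-axis, y-axis, z-axis among file axes
  a <- aperm(a, perm)
  nxyz <- dim(a)
  mg <- ifelse(mgrid <= 0, nxyz, mgrid)   # MX/MY/MZ are already in x,y,z order
  pixel <- cella[1:3] / mg
  ori <- origin
  if (all(abs(origin) < 1e-12) && any(nstart != 0)) {
    ns_xyz <- nstart[perm]
    ori <- ns_xyz * pixel
  } else if (any(nstart != 0)) {
    ns_xyz <- nstart[perm]
    if (any(abs(ns_xyz * pixel - origin) > 1e-3)) {
      message("read_map: ORIGIN and NXSTART disagree; using ORIGIN")
    }
  }
  if (any(pixel <= 0) || any(!is.finite(pixel))) {
    stop("read_map: malformed header: non-positive cell/sampling")
  }
  # cell consistency: the returned map's cell is grid length x pixel size;
  # warn when that differs from the header cell (e.g. a subvolume header).
  if (any(abs(cella - nxyz * pixel) > 1e-3 * pmax(cella, 1))) {
    warning("read_map: header cell inconsistent with grid x pixel size; ",
      "cell recomputed from pixel size")
  }
  voxel_map(a, pixel_size = pixel, origin = ori)
}

#' Write a VoxelMap as MRC2014
#'
#' Writes mode 2 (float32), little-endian, axis order (x, y, z), with the
#' cell computed from the grid and pixel size and the origin stored in the
#' ORIGIN header record.
#'
#' @param map a [voxel_map()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_map <- function(map, path) {
  stopifnot_voxel_map(map)
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("write_map: cannot open for writing: ", path)
  on.exit(close(con))
  endian <- "little"
  d <- dim(map$data)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = endian)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = endian)
  dat <- as.numeric(map$data)
  wi(d)                                   # NX NY NZ
  wi(2)                                   # MODE float32
  wi(c(0, 0, 0))                          # NXSTART..
  wi(d)                                   # MX MY MZ
  wf(d * map$pixel_size)                  # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1, 2, 3))                          # MAPC MAPR MAPS
  wf(c(min(dat), max(dat), mean(dat)))    # DMIN DMAX DMEAN
  wi(1)                                   # ISPG (P1)
  wi(0)                                   # NSYMBT
  wi(rep(0L, 25))                         # EXTRA (words 25-49)
  wf(map$origin)                          # ORIGIN X Y Z (words 50-52)
  writeBin(charToRaw("MAP "), con)        # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST
  wf(stats::sd(dat))                      # RMS
  wi(0)                                   # NLABL
  writeBin(raw(800), con)                 # labels
  writeBin(dat, con, size = 4, endian = endian)
  invisible(path)
}
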