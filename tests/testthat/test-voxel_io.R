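# MRC2014 and coordinate-file input/output

test_that("write/read round trip preserves data and geometry", {
  vm <- fix_random_map(16, seed = 3, pixel = 1.22)
  vm$origin <- c(1, 2, 3)
  vm <- voxel_map(vm$data, 1.22, origin = c(1, 2, 3))
  tf <- tempfile(fileext = ".mrc")
  write_map(vm, tf)
  back <- read_map(tf)
  # float32 storage: values agree to single precision
  expect_lt(max(abs(back$data - vm$data)), 1e-6 * max(abs(vm$data)))
  expect_equal(back$pixel_size, rep(1.22, 3), tolerance = 1e-6)
  expect_equal(back$origin, c(1, 2, 3), tolerance = 1e-6)
  expect_equal(back$cell, dim(vm$data) * 1.22, tolerance = 1e-5)
  # a second round trip is bit-exact (float32 in, float32 out)
  tf2 <- tempfile(fileext = ".mrc")
  write_map(back, tf2)
  expect_identical(readBin(tf, "raw", file.size(tf))[1025:4096],
    readBin(tf2, "raw", file.size(tf2))[1025:4096])
})

test_that("zero map writes an all-zero data block of the right size", {
  vm <- voxel_map(array(0, c(8, 8, 8)), 1)
  tf <- tempfile(fileext = ".mrc")
  write_map(vm, tf)
  expect_equal(file.size(tf), 1024 + 8^3 * 4)
  expect_true(all(readBin(tf, "raw", file.size(tf))[-(1:1024)] == as.raw(0)))
})

test_that("permuted axis order (MAPC/MAPR/MAPS) is normalized to x,y,z", {
  # labelled 4^3 grid: value encodes its logical (x,y,z) index
  n <- 4
  lab <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    lab[i, j, k] <- i * 100 + j * 10 + k
  }
  # write a file whose fastest axis is z, then x, then y: MAPC/R/S = (3,1,2)
  # file array index (c,r,s) holds logical (x=r, y=s, z=c)
  perm_data <- aperm(lab, c(3, 1, 2))
  tf <- tempfile(fileext = ".mrc")
  vm <- voxel_map(perm_data, 1)
  write_map(vm, tf)
  # patch MAPC/MAPR/MAPS words (17:19) to declare the permutation
  con <- file(tf, "r+b")
  seek(con, 64, rw = "write")
  writeBin(as.integer(c(3, 1, 2)), con, size = 4, endian = "little")
  close(con)
  back <- read_map(tf)
  expect_equal(back$data, lab)
})

test_that("malformed headers and bad voxels are rejected with clear errors", {
  vm <- voxel_map(array(1, c(4, 4, 4)), 1)
  tf <- tempfile(fileext = ".mrc")
  write_map(vm, tf)
  # corrupt the MAP tag
  con <- file(tf, "r+b"); seek(con, 208, rw = "write")
  writeBin(charToRaw("XXX "), con); close(con)
  expect_error(read_map(tf), "MAP identifier")
  # NaN voxel
  tf2 <- tempfile(fileext = ".mrc")
  write_map(vm, tf2)
  con <- file(tf2, "r+b"); seek(con, 1024, rw = "write")
  writeBin(NaN, con, size = 4, endian = "little"); close(con)
  expect_error(read_map(tf2), "NaN")
  expect_error(read_map(tempfile()), "no such file")
})

test_that("inconsistent header cell triggers repair with a warning", {
  vm <- voxel_map(array(rnorm(4^3), c(4, 4, 4)), 1.5)
  tf <- tempfile(fileext = ".mrc")
  write_map(vm, tf)
  # declare MX half the grid: pixel becomes cell/MX, cell != nx * pixel
  con <- file(tf, "r+b"); seek(con, 28, rw = "write")
  writeBin(as.integer(c(2, 2, 2)), con, size = 4, endian = "little"); close(con)
  expect_warning(back <- read_map(tf), "cell")
  expect_equal(back$pixel_size, rep(3, 3), tolerance = 1e-6)
  expect_equal(back$cell, rep(12, 3), tolerance = 1e-5)
})

test_that("integer MRC modes are promoted to float on read", {
  # hand-build a mode 1 (int16) file
  tf <- tempfile(fileext = ".mrc")
  vm <- voxel_map(array(0, c(4, 4, 4)), 1)
  write_map(vm, tf)
  vals <- sample(-100:100, 64, replace = TRUE)
  con <- file(tf, "r+b")
  seek(con, 12, rw = "write")
  writeBin(1L, con, size = 4, endian = "little")
  seek(con, 1024, rw = "write")
  writeBin(as.integer(vals), con, size = 2, endian = "little")
  close(con)
  back <- read_map(tf)
  expect_equal(as.vector(back$data), as.numeric(vals))
  expect_type(back$data, "double")
})

test_that("PDB atoms are parsed with position, occupancy, B and element", {
  atoms <- read_atoms(fix_pdb_file())
  expect_equal(nrow(atoms), 3)
  expect_equal(atoms$x, c(1, 2.5, 5))
  expect_equal(atoms$occ, c(1, 0.8, 1))
  expect_equal(atoms$b, c(10, 20, 30))
  expect_equal(atoms$element, c("N", "C", "O"))
})

test_that("altloc pairs collapse to the highest-occupancy conformer", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.30 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.70 10.00           C",
    "END"), tf)
  atoms <- read_atoms(tf)
  expect_equal(nrow(atoms), 1)
  expect_equal(atoms$x, 2)
  expect_equal(atoms$occ, 0.7)
})

test_that("empty coordinate files give an empty atom table", {
  tf <- tempfile(fileext = ".pdb")
  file.create(tf)
  expect_equal(nrow(read_atoms(tf)), 0)
})

test_that("minimal mmCIF atom_site loops parse", {
  tf <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.type_symbol",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "ATOM N 1.0 2.0 3.0 1.0 12.5",
    "ATOM C 4.0 5.0 6.0 0.5 20.0"
  ), tf)
  atoms <- read_atoms(tf)
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$z, c(3, 6))
  expect_equal(atoms$b, c(12.5, 20))
})
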