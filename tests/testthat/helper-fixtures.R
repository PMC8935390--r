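# Shared fixture builders. Everything is generated in code; grids are kept
# small so brute-force oracles stay fast.

fix_random_map <- function(n = 8, seed = 1, pixel = 1) {
  set.seed(seed)
  voxel_map(array(rnorm(n^3), c(n, n, n)), pixel_size = pixel)
}

# standard small phantom + half pair used across modules
fix_phantom_halves <- function(n = 32, snr = 5, seed = 101) {
  spec <- random_phantom_spec(n, 1, n_blobs = 5, seed = seed)
  ph <- make_phantom(spec)
  sigma <- noise_sigma_for_snr(ph, snr)
  halves <- make_half_pair(ph, sigma, seed = seed + 1)
  list(spec = spec, phantom = ph, sigma = sigma,
    half1 = halves$half1, half2 = halves$half2, truth = halves$truth)
}

# brute-force windowed weighted moments at one voxel (periodic), used as
# the independent oracle for the FFT convolution route
bf_local_moment <- function(a1, a2, kernel, ix, iy, iz) {
  d <- dim(a1)
  rad <- kernel$radius
  s11 <- 0; s22 <- 0; s12 <- 0; m1 <- 0; m2 <- 0
  for (ox in -rad:rad) for (oy in -rad:rad) for (oz in -rad:rad) {
    w <- kernel$weights[ox + rad + 1, oy + rad + 1, oz + rad + 1]
    if (w == 0) next
    jx <- (ix - 1 + ox) %% d[1] + 1
    jy <- (iy - 1 + oy) %% d[2] + 1
    jz <- (iz - 1 + oz) %% d[3] + 1
    v1 <- a1[jx, jy, jz]; v2 <- a2[jx, jy, jz]
    m1 <- m1 + w * v1; m2 <- m2 + w * v2
    s11 <- s11 + w * v1 * v1; s22 <- s22 + w * v2 * v2; s12 <- s12 + w * v1 * v2
  }
  list(mean1 = m1, mean2 = m2, var1 = s11 - m1^2, var2 = s22 - m2^2,
    cov12 = s12 - m1 * m2)
}

# a tiny hand-written PDB fragment
fix_pdb_file <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  0.80 20.00           C",
    "ATOM      3  O   HOH B   5       5.000   5.000   5.000  1.00 30.00           O",
    "END"), path)
  path
}
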