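# Kernel construction and local correlation maps

test_that("kernel is normalized, spherical and piecewise as specified", {
  k <- build_kernel(2)            # default r1 = r0 + 2
  expect_equal(k$r1, 4)
  expect_equal(sum(k$weights), 1, tolerance = 1e-9)
  ctr <- k$radius + 1
  # plateau: weight at |x| = 2 equals weight at centre
  expect_equal(k$weights[ctr + 2, ctr, ctr], k$weights[ctr, ctr, ctr])
  # zero at |x| >= r1
  expect_equal(k$weights[ctr + 4, ctr, ctr], 0)
  # half plateau at the raised-cosine midpoint |x| = 3
  expect_equal(k$weights[ctr + 3, ctr, ctr], k$weights[ctr, ctr, ctr] / 2)
  # spherical symmetry
  expect_equal(k$weights[ctr + 3, ctr, ctr], k$weights[ctr, ctr - 3, ctr])

  k0 <- build_kernel(0, 1)
  expect_equal(sum(k0$weights), 1)
  expect_equal(max(k0$weights), k0$weights[k0$radius + 1, k0$radius + 1, k0$radius + 1])
  expect_error(build_kernel(3, 3), "r1")
})

test_that("FFT local moments equal the brute-force windowed oracle", {
  set.seed(12)
  a1 <- array(rnorm(12^3), c(12, 12, 12))
  a2 <- array(rnorm(12^3), c(12, 12, 12))
  k <- build_kernel(2)
  mom <- local_moments(voxel_map(a1, 1), voxel_map(a2, 1), k)
  idx <- cbind(sample(12, 12, TRUE), sample(12, 12, TRUE), sample(12, 12, TRUE))
  for (r in seq_len(nrow(idx))) {
    bf <- bf_local_moment(a1, a2, k, idx[r, 1], idx[r, 2], idx[r, 3])
    expect_equal(mom$cov12[idx[r, 1], idx[r, 2], idx[r, 3]], bf$cov12,
      tolerance = 1e-6)
    expect_equal(mom$var1[idx[r, 1], idx[r, 2], idx[r, 3]], bf$var1,
      tolerance = 1e-6)
    expect_equal(mom$var2[idx[r, 1], idx[r, 2], idx[r, 3]], bf$var2,
      tolerance = 1e-6)
  }
})

test_that("moments are exact on affine pairs and flat maps", {
  set.seed(13)
  a <- array(rnorm(10^3), c(10, 10, 10))
  k <- build_kernel(1.5)
  m1 <- voxel_map(a, 1)
  m2 <- voxel_map(2.5 * a + 3, 1)
  mom <- local_moments(m1, m2, k)
  expect_equal(mom$cov12, 2.5 * mom$var1, tolerance = 1e-8)
  flat <- voxel_map(array(4, c(10, 10, 10)), 1)
  momf <- local_moments(flat, flat, k)
  expect_lt(max(abs(momf$var1)), 1e-12)
  expect_lt(max(abs(momf$cov12)), 1e-12)
})

test_that("correlation map matches a brute-force weighted Pearson", {
  set.seed(14)
  a1 <- array(rnorm(10^3), c(10, 10, 10))
  a2 <- array(rnorm(10^3), c(10, 10, 10)) + 0.5 * a1
  k <- build_kernel(2)
  cc <- cc_from_moments(local_moments(voxel_map(a1, 1), voxel_map(a2, 1), k))
  for (r in 1:8) {
    i <- sample(10, 3, TRUE)
    bf <- bf_local_moment(a1, a2, k, i[1], i[2], i[3])
    expect_equal(cc$values[i[1], i[2], i[3]],
      bf$cov12 / sqrt(bf$var1 * bf$var2), tolerance = 1e-6)
  }
  # perfect linear dependence
  cc1 <- cc_from_moments(local_moments(voxel_map(a1, 1),
    voxel_map(2 * a1, 1), k))
  expect_equal(stats::na.omit(as.vector(cc1$values)), rep(1, 1000),
    tolerance = 1e-6, ignore_attr = TRUE)
  ccm <- cc_from_moments(local_moments(voxel_map(a1, 1),
    voxel_map(-a1, 1), k))
  expect_equal(stats::na.omit(as.vector(ccm$values)), rep(-1, 1000),
    tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("half-to-full conversion is the printed algebra, monotone", {
  v <- array(c(0, 1, 1 / 3, 0.8), c(4, 1, 1))
  cc <- structure(list(values = v, kind = "half"), class = "cc_map")
  out <- cc_half_to_full(cc)
  expect_equal(out$values[1:3], c(0, 1, 0.5))
  expect_equal(out$kind, "full")
  expect_error(cc_half_to_full(out), "half")
  grid <- array(seq(-0.9, 1, length.out = 1000), c(1000, 1, 1))
  g <- cc_half_to_full(structure(list(values = grid, kind = "half"),
    class = "cc_map"))
  expect_true(all(diff(as.vector(g$values)) > 0))
})

test_that("map-model correlation refuses unweighted input unless forced", {
  fx <- fix_phantom_halves(n = 24, seed = 51)
  k <- build_kernel(2)
  expect_error(cc_map_model(fx$half1, fx$half2, k), "weighted")
  expect_s3_class(cc_map_model(fx$half1, fx$half2, k, force = TRUE), "cc_map")
})

test_that("weighted self-correlation is 1 where defined", {
  fx <- fix_phantom_halves(n = 24, snr = 10, seed = 52)
  shells <- make_shells(c(24, 24, 24), 1, nbins = 8)
  st <- estimate_signal_noise(forward_fft(fx$half1), forward_fft(fx$half2),
    shells)
  full <- voxel_map((fx$half1$data + fx$half2$data) / 2, 1)
  w <- weighted_real_map(normalize_and_weight(forward_fft(full), st))
  cc <- cc_map_model(w, w, build_kernel(2))
  vals <- stats::na.omit(as.vector(cc$values))
  expect_true(all(abs(vals - 1) < 1e-6))
})

test_that("atom interpolation of correlation maps is trilinear", {
  set.seed(15)
  v <- array(runif(8^3), c(8, 8, 8))
  cc <- structure(list(values = v, kind = "full"), class = "cc_map")
  map <- voxel_map(v, pixel_size = 2, origin = c(0, 0, 0))
  at_vox <- data.frame(x = 2 * 3, y = 2 * 4, z = 2 * 2)   # voxel (3,4,2)
  res <- atom_cc(cc, at_vox, map)
  expect_equal(res$cc, v[4, 5, 3])
  # midpoint along x between voxels (3,...) and (4,...)
  at_mid <- data.frame(x = 2 * 3.5, y = 2 * 4, z = 2 * 2)
  expect_equal(atom_cc(cc, at_mid, map)$cc, (v[4, 5, 3] + v[5, 5, 3]) / 2)
  # random positions against a direct oracle
  pts <- matrix(runif(30, 0.5, 6.5), ncol = 3)
  oracle <- function(p) {
    f <- floor(p); d <- p - f
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) d[1] else 1 - d[1]) * (if (cy) d[2] else 1 - d[2]) *
        (if (cz) d[3] else 1 - d[3])
      acc <- acc + w * v[f[1] + 1 + cx, f[2] + 1 + cy, f[3] + 1 + cz]
    }
    acc
  }
  got <- atom_cc(cc, data.frame(x = 2 * pts[, 1], y = 2 * pts[, 2],
    z = 2 * pts[, 3]), map)
  expect_equal(got$cc, apply(pts, 1, oracle), tolerance = 1e-12)
  # outside the grid: flagged, not clamped
  out <- atom_cc(cc, data.frame(x = 100, y = 0, z = 0), map)
  expect_true(out$flagged)
  expect_true(is.na(out$cc))
})
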