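# Rigid transforms, Fourier transforms of maps, and the overlay fit

test_that("axis-angle parameterization round-trips and is proper", {
  set.seed(21)
  for (i in 1:10) {
    aa <- stats::rnorm(3, 0, 0.8)
    R <- axis_angle_to_matrix(aa)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    back <- matrix_to_axis_angle(R)
    expect_equal(back, aa, tolerance = 1e-9)
  }
  expect_equal(axis_angle_to_matrix(c(0, 0, 0)), diag(3))
})

test_that("identity transform leaves Fourier coefficients unchanged", {
  vm <- fix_random_map(16, seed = 22)
  f <- forward_fft(vm)
  out <- transform_fourier(f, rigid_transform())
  expect_lt(max(Mod(out$coeffs - f$coeffs)), 1e-12)
})

test_that("pure translation obeys the Fourier shift theorem", {
  vm <- fix_random_map(16, seed = 23)
  f <- forward_fft(vm)
  out <- inverse_fft(transform_fourier(f,
    rigid_transform(translation = c(1, 0, 0))))
  shifted <- vm$data[c(16, 1:15), , ]
  expect_lt(max(abs(out$data - shifted)), 1e-6)
})

test_that("90-degree rotation about z matches the exact lattice rotation", {
  # odd grid so the centre voxel is the exact rotation fixed point and the
  # lattice maps onto itself
  n <- 17
  set.seed(24)
  spec <- random_phantom_spec(n, 1, n_blobs = 4, seed = 24)
  vm <- make_phantom(spec)
  f <- forward_fft(vm)
  got <- inverse_fft(transform_fourier(f,
    rigid_transform(c(0, 0, pi / 2))))
  # exact rotation oracle: (x,y) -> (c - (y-c), c + (x-c)) on indices
  idx <- 1:n; ctr <- (n + 1) / 2
  oracle <- vm$data
  for (i in idx) for (j in idx) {
    src_i <- round(ctr + (j - ctr))
    src_j <- round(ctr - (i - ctr))
    oracle[i, j, ] <- vm$data[src_i, src_j, ]
  }
  # compare inside the resolution sphere (transform zeroes the corners)
  smag <- cryoval:::freq_magnitude(rep(n, 3), rep(1, 3))
  Fo <- stats::fft(oracle); Fg <- stats::fft(got$data)
  inside <- smag <= 0.5
  expect_lt(max(Mod(Fo[inside] - Fg[inside])) / max(Mod(Fo)), 1e-6)
})

test_that("atom transforms compose and invert exactly", {
  atoms <- data.frame(x = c(1, 5), y = c(2, -3), z = c(0, 4),
    occ = 1, b = 0, element = "C")
  t1 <- rigid_transform(c(0.2, -0.4, 0.1), c(1, 2, -0.5))
  ctr <- c(10, 10, 10)
  fwd <- apply_transform_to_atoms(atoms, t1, ctr)
  back <- apply_transform_to_atoms(fwd, invert_transform(t1), ctr)
  expect_equal(back$x, atoms$x, tolerance = 1e-9)
  expect_equal(back$y, atoms$y, tolerance = 1e-9)
  expect_equal(back$z, atoms$z, tolerance = 1e-9)
  # identity and an in-plane flip
  expect_equal(apply_transform_to_atoms(atoms, rigid_transform(), ctr), atoms)
  flip <- apply_transform_to_atoms(atoms, rigid_transform(c(0, 0, pi)), ctr)
  expect_equal(flip$x, 2 * ctr[1] - atoms$x, tolerance = 1e-9)
  expect_equal(flip$y, 2 * ctr[2] - atoms$y, tolerance = 1e-9)
  expect_equal(flip$z, atoms$z, tolerance = 1e-9)
})

test_that("analytic cross-term gradient matches central finite differences", {
  spec <- random_phantom_spec(24, 1, seed = 25)
  ph <- make_phantom(spec)
  mov <- make_transformed_copy(ph,
    rigid_transform(c(0.05, -0.03, 0.08), c(0.7, -0.4, 0.3)))
  prep <- cryoval:::fit_prep(ph, mov, resolution = 3)
  wt <- cryoval:::fit_weights(prep, cryoval:::fit_resample(prep, diag(3), c(0, 0, 0)))
  set.seed(26)
  for (trial in 1:3) {
    par0 <- c(stats::rnorm(3, 0, 0.03), stats::rnorm(3, 0, 0.4))
    g <- cryoval:::fit_objective(par0, prep, wt$fstat, diag(3),
      grad = "interp")$gradient
    gfd <- vapply(1:6, function(k) {
      e <- rep(0, 6); e[k] <- 1e-6
      (cryoval:::fit_objective(par0 + e, prep, wt$fstat, diag(3))$value -
        cryoval:::fit_objective(par0 - e, prep, wt$fstat, diag(3))$value) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g - gfd)) / max(abs(g)), 1e-4)
  }
})

test_that("self-fit from small offsets returns the identity", {
  spec <- random_phantom_spec(32, 1, seed = 27)
  ph <- make_phantom(spec)
  sigma <- noise_sigma_for_snr(ph, 10)
  set.seed(28)
  noisy <- voxel_map(ph$data + array(stats::rnorm(32^3, 0, sigma), c(32, 32, 32)), 1)
  fit0 <- fit_transform(noisy, noisy, resolution = 3, multires = FALSE)
  expect_lt(rotation_angle_deg(fit0$transform), 0.01)
  expect_lt(sqrt(sum(fit0$transform$translation^2)), 0.01)
  # basin: from a deliberate initial offset on a smooth map
  init <- rigid_transform(c(0.03, -0.05, 0.04), c(1.5, -1, 0.8))
  fit1 <- fit_transform(ph, ph, init = init, resolution = 3)
  expect_lt(rotation_angle_deg(fit1$transform), 0.05)
  expect_lt(sqrt(sum(fit1$transform$translation^2)), 0.05)
})

test_that("parameter recovery over random small transforms is accurate", {
  n <- 48
  spec <- random_phantom_spec(n, 1, seed = 29)
  ph <- make_phantom(spec)
  sigma <- noise_sigma_for_snr(ph, 5)
  set.seed(30)
  ang_err <- c(); tr_err <- c()
  for (i in 1:5) {
    aa <- stats::rnorm(3)
    aa <- aa / sqrt(sum(aa^2)) * stats::runif(1, 0.02, 0.26)  # up to 15 deg
    tt <- stats::runif(3, -2.5, 2.5)
    t_true <- rigid_transform(aa, tt)
    mov <- make_transformed_copy(ph, t_true)
    sn <- voxel_map(ph$data + array(stats::rnorm(n^3, 0, sigma), rep(n, 3)), 1)
    mn <- voxel_map(mov$data + array(stats::rnorm(n^3, 0, sigma), rep(n, 3)), 1)
    fit <- fit_transform(sn, mn, resolution = 2.5)
    ti <- invert_transform(t_true)
    # compare rotation magnitudes (as the headline numbers do): the AXIS
    # of a small rotation is intrinsically ill-determined, so a geodesic
    # error would mostly measure that degeneracy rather than the fit
    ang_err <- c(ang_err,
      abs(rotation_angle_deg(fit$transform) - rotation_angle_deg(ti)))
    tr_err <- c(tr_err, sqrt(sum((fit$transform$translation - ti$translation)^2)))
  }
  expect_lt(stats::median(ang_err), 0.1)
  expect_lt(stats::median(tr_err), 0.1)
})

test_that("fitting improves the FSC up to the refinement resolution", {
  spec <- random_phantom_spec(32, 1, seed = 33)
  ph <- make_phantom(spec)
  t_true <- rigid_transform(c(0.06, 0.1, -0.04), c(1.2, -0.8, 0.5))
  mov <- make_transformed_copy(ph, t_true)
  sigma <- noise_sigma_for_snr(ph, 5)
  set.seed(34)
  sn <- voxel_map(ph$data + array(stats::rnorm(32^3, 0, sigma), c(32, 32, 32)), 1)
  mn <- voxel_map(mov$data + array(stats::rnorm(32^3, 0, sigma), c(32, 32, 32)), 1)
  fit <- fit_transform(sn, mn, resolution = 3)
  # shells holding signal before the fit must not degrade; near-zero
  # shells fluctuate either way
  ok <- !is.na(fit$fsc_before) & !is.na(fit$fsc_after) &
    fit$shells$centers <= 1 / fit$resolution & fit$fsc_before > 0.1
  expect_true(all(fit$fsc_after[ok] >= fit$fsc_before[ok] - 0.02))
  expect_gt(mean(fit$fsc_after[ok] - fit$fsc_before[ok]), 0)
})

test_that("score_fit prefers the aligning transform", {
  spec <- random_phantom_spec(24, 1, seed = 35)
  ph <- make_phantom(spec)
  t_true <- rigid_transform(c(0, 0, 0.15), c(1, 0, 0))
  mov <- make_transformed_copy(ph, t_true)
  s_true <- score_fit(ph, mov, invert_transform(t_true), resolution = 3)
  s_id <- score_fit(ph, mov, rigid_transform(), resolution = 3)
  expect_lt(s_true$nll, s_id$nll)
  # self score at identity beats nearby translations
  s0 <- score_fit(ph, ph, rigid_transform(), resolution = 3)
  for (dx in c(-2, -1, 1, 2)) {
    sd <- score_fit(ph, ph, rigid_transform(translation = c(dx, 0, 0)),
      resolution = 3)
    expect_lt(s0$nll, sd$nll)
  }
  # independent noise maps: no shared signal to score
  set.seed(36)
  nz1 <- voxel_map(array(stats::rnorm(24^3), c(24, 24, 24)), 1)
  nz2 <- voxel_map(array(stats::rnorm(24^3), c(24, 24, 24)), 1)
  s_n <- try(score_fit(nz1, nz2, rigid_transform(), resolution = 3), silent = TRUE)
  if (!inherits(s_n, "try-error")) {
    expect_lt(abs(s_n$cross_term) / abs(s_true$cross_term), 0.05)
  }
})

test_that("soft masks extract regions and bound the density", {
  spec <- random_phantom_spec(32, 1, seed = 37)
  ph <- make_phantom(spec)
  ctr <- c(16, 16, 16)
  masked <- extract_masked_region(ph, center = ctr, radius = 6, edge = 3)
  m <- attr(masked, "mask")
  expect_true(all(m >= 0 & m <= 1))
  # zero outside radius + edge
  far <- masked$data[1:3, 1:3, 1:3]
  expect_true(all(far == 0))
  expect_lte(sum(masked$data), sum(pmax(ph$data, 0)) + 1e-9)
  # atom-based mask equals map near the atom
  at <- data.frame(x = 16, y = 16, z = 16, occ = 1, b = 0, element = "C")
  ma <- extract_masked_region(ph, atoms = at, atom_radius = 3, edge = 2)
  expect_equal(ma$data[17, 17, 17], ph$data[17, 17, 17])
  expect_error(extract_masked_region(ph, atoms = at[0, ]), "empty")
})
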