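# Posterior ("expected true") map estimation from N observed maps.
#
# Per resolution shell, the observed maps' correlation matrix rho_o, the
# inferred true-signal correlation matrix rho_s and the per-map sqrt
# full-map FSC form a linear map that turns the vector of normalized
# observed coefficients Eo into the expected normalized true coefficients:
# <Ft> = rho_s . fsc . rho_o^-1 . Eo. With one map this collapses to the
# scalar Wiener-like weighting sqrt(fsc_full) * Eo.

#' Build per-shell correlation matrices for a set of observed maps
#'
#' Each observed map must come with its pair of half maps (or a
#' precomputed [estimate_signal_noise()] result) so per-map signal, noise
#' and FSC are available. Cross-map entries use the full-map cross-power
#' (noise between different maps is independent, so the cross-power is
#' signal). rho_o is ridge-regularized before inversion.
#'
#' @param fulls list of \code{fourier_map}s (the observed full maps).
#' @param halfstats list of shell objects from [estimate_signal_noise()],
#'   one per map, on the same shells.
#' @param shells the common [make_shells()] object.
#' @param ridge ridge added to the diagonal of rho_o.
#' @param min_count bins with fewer coefficients are flagged invalid.
#' @return object of class \code{shell_matrices}: per-bin list with
#'   \code{rho_o}, \code{rho_s}, \code{fsc_diag}, \code{valid}.
#' @export
build_shell_matrices <- function(fulls, halfstats, shells, ridge = 1e-4,
                                 min_count = 5) {
  N <- length(fulls)
  if (length(halfstats) != N) {
    stop("build_shell_matrices: need half-map statistics for every map")
  }
  for (hs in halfstats) {
    if (is.null(hs$signal)) {
      stop("build_shell_matrices: half-map statistics missing; run estimate_signal_noise")
    }
  }
  nb <- shells$nbins
  # per-bin total power of each full map and cross-powers
  totals <- vapply(fulls, function(f) shell_mean(Mod(f$coeffs)^2, shells),
    numeric(nb))
  totals <- matrix(totals, nrow = nb)
  cross <- array(0, c(nb, N, N))
  for (i in seq_len(N)) {
    cross[, i, i] <- totals[, i]
    if (i < N) for (j in (i + 1):N) {
      cij <- shell_mean(Re(fulls[[i]]$coeffs * Conj(fulls[[j]]$coeffs)), shells)
      cross[, i, j] <- cij
      cross[, j, i] <- cij
    }
  }
  signal <- vapply(halfstats, function(h) h$signal, numeric(nb))
  signal <- matrix(signal, nrow = nb)
  fscfull <- vapply(halfstats, function(h) h$fsc_full, numeric(nb))
  fscfull <- matrix(fscfull, nrow = nb)
  bins <- vector("list", nb)
  for (b in seq_len(nb)) {
    valid <- shells$counts[b] >= min_count &&
      all(is.finite(totals[b, ])) && all(totals[b, ] > 0)
    if (!valid) {
      bins[[b]] <- list(valid = FALSE)
      next
    }
    Tb <- cross[b, , , drop = TRUE]
    Tb <- matrix(Tb, N, N)
    den_o <- sqrt(totals[b, ] %o% totals[b, ])
    rho_o <- Tb / den_o
    diag(rho_o) <- 1
    rho_o <- pmin(pmax(rho_o, -1), 1)
    # eigenvalue floor: estimated correlation matrices can be indefinite;
    # a 1x1 correlation matrix is exactly 1 and needs none (keeping the
    # N = 1 reduction to sqrt(fsc_full) exact)
    rho_o_r <- if (N > 1) rho_o + diag(ridge, N) else rho_o
    Sb <- pmax(signal[b, ], 0)
    rho_s <- matrix(1, N, N)
    if (N > 1) {
      den_s <- sqrt(Sb %o% Sb)
      off <- which(upper.tri(rho_s) | lower.tri(rho_s))
      rho_s[off] <- ifelse(den_s[off] > 0,
        Tb[off] / pmax(den_s[off], 1e-300), 0)
      rho_s <- pmin(pmax(rho_s, -1), 1)
      diag(rho_s) <- 1
    }
    fd <- fscfull[b, ]
    fd <- ifelse(is.na(fd) | fd <= 0, 0, sqrt(pmax(fd, 0)))
    bins[[b]] <- list(valid = TRUE, rho_o = rho_o_r, rho_s = rho_s,
      fsc_diag = fd)
  }
  structure(list(bins = bins, N = N, shells = shells, ridge = ridge),
    class = "shell_matrices")
}

#' Posterior mean ("expected true") maps
#'
#' Applies the per-bin matrix \code{rho_s fsc rho_o^-1} to the vector of
#' normalized observed coefficients at every reciprocal point, returning
#' one posterior map per input. Invalid bins (and points beyond the
#' resolution limit) produce zero coefficients. Inputs must be plain
#' normalized coefficients (Eo), i.e. [normalize_and_weight()] with
#' \code{weight = FALSE}.
#'
#' @param eos list of normalized \code{fourier_map}s (Eo), one per map.
#' @param matrices a [build_shell_matrices()] result.
#' @return list of \code{fourier_map}s of the posterior means (normalized
#'   units).
#' @export
posterior_mean <- function(eos, matrices) {
  stopifnot(inherits(matrices, "shell_matrices"))
  N <- matrices$N
  if (length(eos) != N) stop("posterior_mean: need one Eo map per input map")
  shells <- matrices$shells
  shape <- eos[[1]]$shape
  E <- vapply(eos, function(e) as.vector(e$coeffs), complex(prod(shape)))
  E <- matrix(E, ncol = N)
  out <- matrix(0i, nrow = nrow(E), ncol = N)
  binv <- as.vector(shells$bin)
  for (b in seq_len(shells$nbins)) {
    mb <- matrices$bins[[b]]
    if (!isTRUE(mb$valid)) next
    M <- tryCatch(
      mb$rho_s %*% diag(mb$fsc_diag, N) %*% solve(mb$rho_o),
      error = function(e) NULL
    )
    if (is.null(M)) {
      warning("posterior_mean: singular rho_o in bin ", b, "; bin dropped")
      next
    }
    idx <- which(!is.na(binv) & binv == b)
    out[idx, ] <- E[idx, , drop = FALSE] %*% t(M)
  }
  lapply(seq_len(N), function(j) {
    as_fourier_map(array(out[, j], shape), eos[[j]])
  })
}
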