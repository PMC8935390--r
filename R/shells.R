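# Resolution shells, FSC and per-shell signal/noise statistics.
#
# Fourier coefficients are grouped into bins uniform in |s| (1/Angstrom) up
# to a resolution limit. All per-shell estimators (FSC, signal and noise
# power, normalization weights) live on these bins.

#' Build resolution shells for a grid
#'
#' Every reciprocal-lattice point with |s| <= 1/resolution_limit is assigned
#' to exactly one bin; bins are uniform in |s|. Points beyond the limit get
#' bin NA and are excluded from all shell statistics.
#'
#' @param shape grid dimensions (length 3).
#' @param pixel_size pixel size in Angstrom (scalar or length 3).
#' @param resolution_limit high-resolution cutoff in Angstrom; default the
#'   grid Nyquist limit \code{2 * max(pixel_size)}.
#' @param nbins number of bins; default \code{max(shape) %/% 2}.
#' @return object of class \code{shell_stats} holding the bin assignment
#'   array (\code{bin}), \code{edges}, bin \code{centers} (1/Angstrom),
#'   per-bin \code{counts}, and slots filled by the estimators
#'   ([estimate_signal_noise()], [fsc()]).
#' @export
make_shells <- function(shape, pixel_size = 1, resolution_limit = NULL,
                        nbins = NULL) {
  pixel_size <- rep_len(as.numeric(pixel_size), 3L)
  nyquist_res <- 2 * max(pixel_size)
  resolution_limit <- resolution_limit %||% nyquist_res
  if (resolution_limit < nyquist_res - 1e-9) {
    stop("make_shells: resolution limit ", resolution_limit,
      " A is beyond the grid Nyquist limit (", nyquist_res, " A)")
  }
  nbins <- nbins %||% max(2L, max(shape) %/% 2L)
  smax <- 1 / resolution_limit
  smag <- freq_magnitude(shape, pixel_size)
  width <- smax / nbins
  bin <- floor(smag / width) + 1L
  bin[bin > nbins & smag <= smax + 1e-12] <- nbins  # points exactly at smax
  bin[smag > smax + 1e-12] <- NA_integer_
  storage.mode(bin) <- "integer"
  counts <- tabulate(bin, nbins)
  structure(
    list(
      bin = bin,
      nbins = nbins,
      edges = seq(0, smax, length.out = nbins + 1),
      centers = (seq_len(nbins) - 0.5) * width,
      counts = counts,
      shape = shape,
      pixel_size = pixel_size,
      resolution_limit = resolution_limit
    ),
    class = "shell_stats"
  )
}

# per-bin mean of a real vector; empty bins give NA
shell_mean <- function(values, shells) {
  keep <- !is.na(shells$bin)
  sums <- rep(NA_real_, shells$nbins)
  tb <- rowsum(values[keep], shells$bin[keep])
  idx <- as.integer(rownames(tb))
  sums[idx] <- tb[, 1] / shells$counts[idx]
  sums
}

check_same_grid <- function(f1, f2) {
  if (!all(f1$shape == f2$shape)) stop("maps are on different grids")
  if (any(abs(f1$pixel_size - f2$pixel_size) > 1e-6 * f1$pixel_size)) {
    stop("maps have different pixel sizes")
  }
  invisible(TRUE)
}

#' Fourier shell correlation between two maps
#'
#' Per bin: \code{Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)},
#' clamped to [-1, 1]. Empty bins are reported as NA, never as zero.
#'
#' @param f1,f2 \code{fourier_map}s on the same grid.
#' @param shells a [make_shells()] object for that grid.
#' @return numeric vector of per-bin FSC values.
#' @export
fsc <- function(f1, f2, shells) {
  stopifnot(inherits(f1, "fourier_map"), inherits(f2, "fourier_map"))
  check_same_grid(f1, f2)
  num <- shell_mean(Re(f1$coeffs * Conj(f2$coeffs)), shells)
  d1 <- shell_mean(Mod(f1$coeffs)^2, shells)
  d2 <- shell_mean(Mod(f2$coeffs)^2, shells)
  den <- sqrt(d1 * d2)
  out <- ifelse(is.na(den) | den <= 0, NA_real_, num / den)
  pmin(pmax(out, -1), 1)
}

#' Convert half-map FSC to full-map FSC
#'
#' Element-wise \code{2 f / (1 + f)}; the value at f = -1 is undefined and
#' reported as NA. The mapping is strictly increasing on (-1, 1] and fixes
#' 0 and 1.
#'
#' @param fsc_half per-bin half-map FSC values in (-1, 1].
#' @return per-bin full-map FSC values.
#' @export
half_to_full_fsc <- function(fsc_half) {
  out <- 2 * fsc_half / (1 + fsc_half)
  out[!is.na(fsc_half) & fsc_half <= -1] <- NA_real_
  out
}

#' Estimate per-shell signal and noise from a pair of half maps
#'
#' The two half maps share the underlying signal and carry independent
#' noise, so per bin the real cross-power estimates the signal power S and
#' the mean auto-power T the total; the half-map noise power is T - S
#' (clamped at zero, as is negative S). Also records the half-map FSC, its
#' full-map conversion, and the full-map noise power \code{sigma2_full =
#' sigma2_half / 2} (averaging the halves halves the noise variance).
#'
#' @param h1,h2 \code{fourier_map}s of the two half maps.
#' @param shells a [make_shells()] object.
#' @param min_count bins with fewer coefficients are flagged unreliable.
#' @return the \code{shells} object with fields \code{signal},
#'   \code{noise_half}, \code{noise_full}, \code{total_half},
#'   \code{fsc_half}, \code{fsc_full} and logical \code{reliable} added.
#' @export
estimate_signal_noise <- function(h1, h2, shells, min_count = 5) {
  check_same_grid(h1, h2)
  cross <- shell_mean(Re(h1$coeffs * Conj(h2$coeffs)), shells)
  p1 <- shell_mean(Mod(h1$coeffs)^2, shells)
  p2 <- shell_mean(Mod(h2$coeffs)^2, shells)
  total <- (p1 + p2) / 2
  signal <- pmax(cross, 0)
  noise <- pmax(total - signal, 0)
  den <- sqrt(p1 * p2)
  fh <- pmin(pmax(ifelse(den > 0, cross / den, NA_real_), -1), 1)
  shells$signal <- signal
  shells$total_half <- total
  shells$noise_half <- noise
  shells$noise_full <- noise / 2
  shells$fsc_half <- fh
  shells$fsc_full <- half_to_full_fsc(fh)
  shells$reliable <- shells$counts >= min_count
  shells
}

#' Normalize and FSC-weight the Fourier coefficients of a map
#'
#' Each coefficient is divided by the per-bin total standard deviation
#' \code{sqrt(S + sigma2)} (giving normalized coefficients of unit expected
#' power), then optionally multiplied by \code{sqrt(fsc_full)} of its bin.
#' Bins with non-positive \code{fsc_full}, zero total variance, or beyond
#' the resolution limit are zeroed. All maps entering a map-versus-model
#' local correlation must pass through this weighting so the two
#' correlations are on the same scale.
#'
#' @param fm a \code{fourier_map} (full map or model map).
#' @param stats shells with signal/noise fields from
#'   [estimate_signal_noise()]. The normalization always uses the map's own
#'   per-bin power; the FSC weight comes from \code{stats$fsc_full}.
#' @param weight multiply by \code{sqrt(fsc_full)} (default TRUE); set
#'   FALSE to obtain plain normalized coefficients (E values).
#' @return a \code{fourier_map} with attribute \code{normalized = TRUE} and
#'   \code{weighted} as requested.
#' @export
normalize_and_weight <- function(fm, stats, weight = TRUE) {
  stopifnot(inherits(fm, "fourier_map"), inherits(stats, "shell_stats"))
  if (is.null(stats$fsc_full) && weight) {
    stop("normalize_and_weight: shells carry no fsc_full; run estimate_signal_noise first")
  }
  power <- shell_mean(Mod(fm$coeffs)^2, stats)
  scale_bin <- ifelse(is.na(power) | power <= 0, 0, 1 / sqrt(power))
  if (any(power <= 0, na.rm = TRUE)) {
    warning("normalize_and_weight: zero-power bin(s) zeroed")
  }
  if (weight) {
    w <- stats$fsc_full
    w <- ifelse(is.na(w) | w <= 0, 0, sqrt(pmax(w, 0)))
    scale_bin <- scale_bin * w
  }
  fac <- array(0, dim = fm$shape)
  ok <- !is.na(stats$bin)
  fac[ok] <- scale_bin[stats$bin[ok]]
  out <- as_fourier_map(fm$coeffs * fac, fm)
  attr(out, "normalized") <- TRUE
  attr(out, "weighted") <- weight
  out
}
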