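---
title: "Methods: local correlation, likelihood overlay and magnification refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local correlation, likelihood overlay and magnification refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoval)
```

## Scope

`cryoval` implements post-reconstruction validation and comparison tools
for single-particle cryo-EM: kernel-weighted local correlation between
maps (half-map signal and map-versus-model agreement), Fourier shell
correlation (FSC) and per-shell signal/noise estimation, likelihood-based
rigid-body superposition of one map onto another, refinement of a scalar
relative magnification (equivalently, a pixel-size error), and posterior
("expected true") map estimation from several observed maps. Everything is
exercised on synthetic Gaussian-blob phantoms so the entire test suite
runs without external data.

## Local correlation

For two maps $\psi_1, \psi_2$ and a normalized kernel $m(x)$, the local
correlation at voxel $x$ is the kernel-weighted Pearson coefficient

$$ CC_{12,m}(x) = \frac{\mathrm{cov}_{12,m}(x)}
   {\sqrt{\mathrm{var}_{1,m}(x)\,\mathrm{var}_{2,m}(x)}}, \qquad
   \mathrm{cov}_{12,m} = m * (\psi_1\psi_2) - (m*\psi_1)(m*\psi_2), $$

with the variances defined analogously. All convolutions are evaluated by
FFT, which makes them circular: voxels within one kernel radius of a face
mix density from the opposite face. Users comparing maps near box edges
should pad or mask first; the phantoms used in the tests keep their
content well inside the box.

The kernel is spherically symmetric: flat ($1/Z$) inside radius $r_0$,
raised-cosine from $r_0$ to $r_1$, zero outside, with $r_1 = r_0 + 2$
voxels by default so two voxels soften the mask edge. $Z$ normalizes the
*discrete* sum over voxel centres to exactly 1 (rather than the continuous
integral), so local moments are exact weighted sums. The kernel radius
trades locality against statistical stability; it is exposed to the user
(CLI default $r_0 = 3$) because the appropriate size depends on resolution
and map size, and is best chosen by inspection.

Half-map correlation estimates local signal-to-noise; it is converted to
the full-map scale by the standard mapping $CC_\mathrm{full} =
2c/(1+c)$, which is strictly increasing and fixes 0 and 1. Note that for
$c<0$ (solvent regions at low signal) the mapping can produce values below
$-1$; such voxels mean "no signal", not "anticorrelation at full-map
scale".

Comparing the map-versus-model correlation with $CC_\mathrm{full}$
requires both maps on a common amplitude scale: all Fourier coefficients
are first divided by the per-shell total standard deviation and then
multiplied by the square root of the full-map FSC of the shell
(`normalize_and_weight()`). `cc_map_model()` refuses inputs that have not
been weighted (a `force` flag exists for diagnostics). Under an additive,
model-independent noise assumption the product relation
$CC_\mathrm{map,model} = CC_\mathrm{true}\cdot CC_\mathrm{full}$ holds, so
$CC_\mathrm{map,model} \le CC_\mathrm{full}$ absent overfitting; the test
suite checks this inequality voxel-wise on phantoms with a perfect
pseudo-atom model, within three local sampling errors (the sampling error
uses the kernel's effective sample size $n_\mathrm{eff} = 1/\sum w_i^2$).
Per-atom values are read out of correlation maps by trilinear
interpolation; atoms outside the grid or in undefined (flat-variance)
regions are flagged rather than clamped.

## Shell statistics

Reciprocal space is divided into bins uniform in $|s|$ up to a resolution
limit (default: the grid Nyquist; default bin count: half the largest grid
dimension). Bins beyond the limit are excluded everywhere, and empty bins
are reported as missing, never as zero. From a half-map pair the per-shell
real cross-power estimates the signal power $S$, the mean auto-power the
total $T$, and the half-map noise is $\max(T-S,0)$ (negative estimates are
clamped; the full map, being the average of the halves, carries half that
noise power). This moment decomposition is used instead of an FSC-derived
noise estimate because it is equivalent in expectation and numerically
stabler in shells where the FSC estimate is noisy.

## Likelihood overlay

With per-shell covariances fixed, the transform-dependent part of the
pairwise map likelihood is the weighted cross-term
$C(R,t) = \sum_s w(|s|)\,\mathrm{Re}[\overline{F_1(s)}\,F_2'(s;R,t)]$,
where $F_2'$ is the moving map under rotation $R$ (about the grid-centre
voxel), translation $t$, and optionally a scalar magnification. The
per-bin weight is the off-diagonal of the inverse $2\times2$ total
covariance of the two maps at the current alignment — an increasing
function $r/(1-r^2)$ of the observed shell correlation $r$ (normalized per
shell); shells with $r \le 0$, or with negligible power (where $r$ is
numerical noise), get zero weight, and $r$ is capped at 0.99 so a
noise-free self-comparison cannot blow up the weights.

The iteration follows the classic estimate-then-step cycle: (1) weights
are recomputed at the current alignment, (2) the six parameters
(axis-angle rotation composed multiplicatively, translation) are updated
by a line-searched quasi-Newton (BFGS) step driven by the analytic
gradient of $C$, (3) the loop stops when the relative functional change
falls below $10^{-6}$ or an iteration cap is reached, returning the
best-seen state flagged not-converged if the functional stops improving.
A first pass at twice the resolution cutoff (on by default) widens the
convergence basin. A quasi-Newton update was preferred over plain
backtracking gradient ascent because the six-parameter problem is
anisotropic (rotation and translation curvatures differ by the effective
content radius) and BFGS handles that scaling automatically with the same
gradient information.

Two numerical choices deserve note:

* **Where the cross-term is evaluated.** By Parseval's identity the
  Fourier cross-term equals (up to a constant) the real-space inner
  product of the weight-filtered static map with the resampled moving map.
  We evaluate it in real space. Interpolating the moving *spectrum*
  instead makes the objective non-smooth at lattice-commensurate poses: at
  the identity every sampling point lies exactly on the reciprocal
  lattice, and an infinitesimal rotation attenuates precisely the
  signal-carrying coefficients, creating a spurious kinked maximum that
  stalls every line search. Resampling in real space only attenuates the
  moving map's noise off-lattice — which is uncorrelated with the static
  map — so the objective is smooth in the parameters.
* **Interpolation accuracy.** The moving map (and its gradient fields) are
  kept on a 2× band-limited (Fourier zero-padded) grid before trilinear
  gathering; on the original grid the pose-dependent part of the
  interpolation smoothing is large enough to bias recovered rotations by
  ~0.1–0.2° under the test conditions. The optimizer uses band-limited
  analytic gradient fields (FFT derivatives of the moving map); the exact
  derivative of the discrete trilinear objective is also implemented and
  is the one compared against central finite differences in the tests.

`transform_fourier()` (the public coefficient-domain transform) resamples
the *centred* spectrum — the map is circularly shifted so the grid-centre
voxel sits at the origin before interpolation — because the spectrum of a
centred object carries a steep phase ramp that trilinear interpolation
cannot follow.

## Magnification refinement

A relative magnification $m$ of the moving map enters the same cross-term
by scaling the frequencies at which the moving map is sampled (a diagonal
matrix with one parameter in place of the rotation), never by a real-space
zoom, keeping the objective differentiable and band-limit aware.
`refine_magnification()` alternates the rigid fit with a bracketed 1-D
search over the scalar (bracket half-width 0.03 per cycle, hard abort
outside [0.8, 1.25], up to 20 cycles) until the joint functional
converges. Reported quantities follow the pixel-size arithmetic
convention: `magnification` is the moving map's real-space scale relative
to the reference ($-5\%$ means its features are 5% too small), and the
corrected pixel size is the moving map's nominal pixel size divided by
that magnification — so a map mislabelled 0.998 Å against a 1.05 Å
reference reports a $\approx-5\%$ error and a corrected pixel of 1.05 Å.

Maps on different grids are first resampled onto the reference geometry:
by Fourier cropping/padding when the physical extents agree (exact for
band-limited content), otherwise by real-space interpolation of the voxel
values at the target grid's physical coordinates. The principal-axes
pre-aligner (`pca_prealign()`) orients grossly misaligned maps by
diagonalizing the density-weighted second-moment matrices (negative
density clipped at zero), trying the four proper sign assignments and
keeping the best real-space overlap; near-spherical moment spectra are
flagged degenerate and left at the identity.

## Posterior maps

Given $N$ observed maps with half-map pairs, per shell we assemble the
observed correlation matrix $\rho_o$, the true-signal correlation matrix
$\rho_s$ (cross-map noise is independent, so cross-powers estimate signal)
and the diagonal of $\sqrt{\mathrm{FSC}_\mathrm{full}}$; the expected true
normalized coefficients are $\langle F_t\rangle = \rho_s\,\mathrm{fsc}\,
\rho_o^{-1} E_o$ applied per reciprocal point. The unnormalized form
involving the unknown per-map blurring diagonal is not implemented —
observations alone cannot determine it — and the normalized form is used
exclusively. $\rho_o$ is ridge-regularized ($\varepsilon = 10^{-4}$)
because duplicated or near-duplicate inputs make it singular; for a single
map no ridge is needed (a $1\times1$ correlation is exactly 1), so the
$N=1$ case reduces *exactly* to per-shell $\sqrt{\mathrm{FSC}_\mathrm{full}}$
Wiener-style weighting. The ridge perturbs the duplicated-map case away
from the $N=1$ result by $O(\varepsilon)$; outputs remain exactly
exchangeable and real in real space.

## Synthetic phantoms and what the tests do (and do not) show

The generator builds sums of isotropic 3D Gaussians with reproducible
random centres, widths and amplitudes. The default study phantom (48³
voxels, 1 Å pixels, 16 blobs with widths 1.5–2.8 Å clustered around the
box centre) is chosen to resemble a small protein density at intermediate
resolution: enough high-frequency structure that an orientation is well
determined, content well inside the box so circular convolution and
periodic resampling do not wrap it. Half maps are emulated as phantom plus
independent white Gaussian noise; the SNR quoted in tests is the ratio of
map variance to per-half noise variance. White noise was preferred over
coloured noise because every estimator under test operates per shell, so a
flat spectrum exercises all of them while keeping analytic expectations
exact.

Transformed and magnified ground-truth copies are produced by a real-space
trilinear resampler (`make_transformed_copy()`), a code path deliberately
separate from the Fourier-based machinery the fits use, so that recovery
tests are not self-confirming. The resampler gathers from a 2×
band-limited upsampled grid; with single-grid trilinear gathering the
injected copy carries a grid-locked anisotropic smoothing that measurably
biases rotation recovery (~+0.15° under the standard conditions).

What passing these tests shows: the estimators are internally consistent,
unbiased at the simulated noise levels, and recover injected ground truth
within the stated tolerances. What they do not show: behaviour under
structured (coloured, masked, or alignment-correlated) noise, CTF
artefacts, preferred-orientation anisotropy, or map symmetry — real
reconstructions violate the white-noise, isotropic assumptions in ways the
phantoms do not emulate.

## Problem sizes and runtimes

Unit oracles run on 8³–16³ grids (brute-force windowed moments on 12³);
statistical checks on 24³–32³; the parameter-recovery experiments on 48³
with fits to 2.5 Å (pixel 1 Å) and the magnification experiment to
3.5 Å. These sizes put thousands of coefficients in every informative
shell while keeping each recovery experiment around a minute.

## Known limitations

* Orthogonal (P1) grids only; non-orthogonal cells are rejected at read.
* The overlay likelihood is implemented for a map pair, not a joint
  N-map refinement.
* Magnification is a single scalar; anisotropic magnification is out of
  scope.
* The local-correlation edge behaviour is periodic (see above).
* Masked-FSC corrections, conical/anisotropic FSC and per-residue
  aggregation are not provided.
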