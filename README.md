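# cryoval

Validation and comparison tools for single-particle cryo-EM density maps
and atomic models, in R.

After a cryo-EM reconstruction is finished, three practical questions
remain: *where* in the map is there real signal, *how well* does an atomic
model explain that signal locally, and are two related maps on the same
geometric footing (orientation, position, magnification) before they are
compared? `cryoval` addresses all three with a common statistical
machinery built on resolution-shell statistics of Fourier coefficients:

* **Local correlation maps.** For maps $\psi_1,\psi_2$ and a soft
  spherical kernel $m$ (flat to radius $r_0$, raised-cosine to $r_1 = r_0
  + 2$ voxels), the voxel-wise kernel-weighted Pearson correlation
  $CC_{12,m}(x)$ is computed by FFT convolution. Between half maps it
  measures local signal-to-noise; converted to the full-map scale by
  $CC_\mathrm{full} = 2c/(1+c)$ it is directly comparable to the local
  map-versus-model correlation $CC_\mathrm{map,model}$ (computed on
  per-shell normalized, FSC-weighted maps), for which
  $CC_\mathrm{map,model} \le CC_\mathrm{full}$ holds absent overfitting.
  Per-atom values are interpolated at atomic positions.
* **Likelihood map overlay.** A rigid transform of one map onto another is
  estimated by maximizing the FSC-weighted Fourier cross-term
  $\sum_s w(|s|)\,\mathrm{Re}[\overline{F_1}F_2(R^\top s)e^{-2\pi i s\cdot t}]$,
  with per-shell weights re-estimated from the maps at each iteration and
  analytic gradients driving a line-searched quasi-Newton update.
* **Magnification refinement.** A scalar relative magnification (pixel-size
  error) enters the same likelihood as a diagonal frequency scaling and is
  refined jointly with the rigid pose.
* **Posterior maps.** From $N$ observed maps with half-map pairs, per-shell
  correlation matrices give the expected "true" maps
  $\langle F_t\rangle = \rho_s\,\mathrm{fsc}\,\rho_o^{-1}E_o$ (for one map:
  $\sqrt{\mathrm{FSC}_\mathrm{full}}$ Wiener-style weighting).

Everything runs on plain MRC2014 maps (built-in reader/writer) and
PDB/mmCIF-subset coordinates, and a synthetic phantom generator makes the
whole package testable offline. See the methods vignette
(`vignettes/map-validation-methods.Rmd`) for models, assumptions and
numerical choices.

## Worked example

Simulate a phantom with half maps, compute local correlation, and overlay
a transformed copy:

```r
library(cryoval)

spec    <- random_phantom_spec(48, pixel_size = 1, seed = 7)
phantom <- make_phantom(spec)
sigma   <- noise_sigma_for_snr(phantom, 5)
halves  <- make_half_pair(phantom, sigma, seed = 1)

# local signal: half-map correlation -> full-map scale
kern   <- build_kernel(3)
ccfull <- cc_half_to_full(cc_halfmap(halves$half1, halves$half2, kern))
median(ccfull$values, na.rm = TRUE)
#> [1] 0.03506473   # solvent-dominated voxels pull the median down
quantile(ccfull$values[phantom$data > 0.3], 0.5, na.rm = TRUE)
#> 0.9866728       # inside the molecule the signal is strong

# overlay: recover an injected rotation/translation
t_true <- rigid_transform(c(1, 2, 3) / sqrt(14) * 8.35 * pi / 180,
                          rep(4.14 / sqrt(3), 3))
moving <- make_transformed_copy(phantom, t_true)
fit    <- fit_transform(phantom, moving, resolution = 2.5)
fit
#> <fit_state: rotation 8.344 deg, translation 4.130 A, nll -4.622e+05,
#>  converged in 6 iterations>
```

The recovered transform is the inverse of the injected one: on this
noise-free input the rotation angle matches the injected 8.35 degrees to
0.006 and the translation magnitude the injected 4.14 A to 0.01; at a
signal-to-noise ratio of 5 both typically stay within 0.1 of the truth.

A command-line entry point is installed as `exec/cryoval`, with
subcommands `fsc`, `cc`, `modelmap`, `overlay`, `magref`, `posterior` and
`simulate`; each writes a machine-readable `*_results.json` next to its
outputs. For example:

```sh
cryoval simulate --shape 48 --snr 5 --seed 3 --out sim/
cryoval fsc --half1 sim/half1.mrc --half2 sim/half2.mrc --out sim/
cryoval overlay --static sim/fullmap.mrc --moving moved.mrc --resolution 2.5
```

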