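Package: cryoval
Title: Validation and Comparison Tools for Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for post-reconstruction validation and comparison of
    single-particle cryo-EM density maps and atomic models. Provides
    kernel-weighted local correlation maps from half maps and model-derived
    maps (including the half-to-full map conversion and per-atom correlation
    readout), Fourier shell correlation and per-shell signal/noise
    estimation, likelihood-based rigid-body superposition of maps,
    refinement of a relative magnification (pixel-size) factor against a
    reference map or model, and Bayesian posterior map estimation from
    several observed maps. Includes MRC2014 map input/output, a minimal
    coordinate-file reader, a Gaussian-atom model-map generator, and a
    synthetic phantom generator so that the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
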