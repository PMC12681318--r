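Package: eapsim
Title: Exact Sampling of Ensemble Average Propagators and Spin-Level
    Diffusion MRI Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Draws exact random displacement samples from arbitrary
    non-Gaussian Ensemble Average Propagators (EAPs) -- diffusion tensors,
    MAP-MRI Hermite-function expansions, and spherical-convolution models
    built from spherical-harmonic fiber orientation distributions -- via
    rejection sampling with automatically constructed wrapper densities.
    Sampled displacements drive spin-level Monte-Carlo simulation of
    pulsed-gradient spin-echo (PGSE) diffusion-weighted MRI, with
    synthetic phantom generators, FSL-style gradient-table handling, and
    validation metrics (normalized mean squared error, Fisher-tested
    Pearson correlation maps, log-linear diffusion tensor fitting and
    color orientation maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
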