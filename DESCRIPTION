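Package: blushr
Title: Denoiser-Regularized Cryo-EM Map Refinement with Spectral Trailing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regularizing single-particle cryo-EM reconstruction with
    a learned volumetric denoiser in the style of Blush regularization. Provides
    MRC2014 volume input/output, Fourier-shell machinery (FSC, solvent-corrected
    FSC with phase randomization, shell filters, anisotropic Gaussian filters,
    colored-noise synthesis), noise2noise training-pair augmentation from
    half-map pairs, a residual 3D U-net denoiser trained with a recycling loss,
    a toy iterative refinement loop with spectral trailing, and synthetic
    phantom data generators so the whole pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
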