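Package: ttquant
Title: Quantification of Cardiomyocyte T-System Remodeling from 3D Confocal Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify transverse tubular system (t-system) remodeling,
    excitation-contraction coupling junction integrity and extracellular matrix
    fraction in cardiomyocytes imaged by 3D confocal microscopy. Provides image
    restoration (median/Gaussian denoising, Richardson-Lucy deconvolution,
    depth-attenuation correction, linear spectral unmixing), membrane and cell
    segmentation (anisotropy-aware 3D watershed, morphological closing, surface
    versus t-system classification), t-system morphometry (anisotropic Euclidean
    distance maps, volume density, skeleton-based volume-to-length ratio),
    protein cluster and co-localization analysis (LTCC, RyR, JPH2), WGA-based
    extracellular matrix quantification, a hierarchical statistics layer
    (linear mixed-effects models with per-sample random intercepts, one-way
    ANOVA, Welch t-tests, Holm-Bonferroni correction), and a ground-truthed
    synthetic phantom generator with a confocal imaging forward model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
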