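Package: panelIQ
Title: Image Quality Characterization of Flat-Panel X-Ray Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the physical image-quality characterization of digital
    radiography flat-panel detectors: presampled modulation transfer function
    (MTF) from tilted-edge images, normalized noise power spectrum (NNPS) from
    flat-field series using half-overlapping regions of interest, detective
    quantum efficiency (DQE) under standardized RQA beam qualities, and
    phantom contrast-to-noise ratio (CNR) and coefficient of variation (COV).
    Includes a Poisson-Gaussian imaging-chain simulator of an
    indirect-conversion detector with analytically known MTF and NNPS, so
    every estimator can be validated against closed-form ground truth, and an
    image restoration module (PSF synthesis from a measured MTF, adaptive
    noise pre-filtering, Wiener deconvolution).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'registry.R'
    'simulate.R'
    'mtf.R'
    'nnps.R'
    'dqe.R'
    'phantom.R'
    'restore.R'
    'io.R'
    'pipeline.R'
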