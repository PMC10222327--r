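Package: deblurMSI
Title: Automated Deblurring and Resolution Measurement for Mass
    Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Software-only resolution enhancement for ambient mass
    spectrometry imaging (MSI). Estimates the effective point spread
    function width (2 sigma, in pixels) of a single ion image from
    intensity profiles perpendicular to automatically detected straight
    edges, runs blind Richardson-Lucy deconvolution whose initial PSF
    guess and termination are driven by that estimator, and measures
    effective spatial resolution by single-image Fourier ring correlation
    against the half-bit information threshold. Includes a synthetic
    phantom generator with known ground-truth blur, noise and missing
    pixels, imzML/ibd and plain-image I/O, and batch orchestration with
    one-sided Wilcoxon signed-rank before/after comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    tiff,
    png,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
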