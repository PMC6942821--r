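Package: stripwave
Title: Wavelet Denoising and Quantification for Fluorescence Lateral-Flow Strip Scans
Version: 0.1.0
Authors@R: person("Strip", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signal analysis for fluorescence immunochromatographic (lateral-flow)
    strip readers. Implements discrete wavelet threshold denoising of 1-D line
    scans with hard, soft and an improved shrinkage threshold function, a
    level-dependent threshold selection rule, and SNR/RMSE benchmarking on
    standard test signals. Downstream tools extract control (C) and test (T)
    band intensities, compute the T/C characteristic value, fit and invert
    linear calibration curves, and report assay QC statistics (replicate
    mean/SD/CV and blank-based limit-of-detection assessment). A synthetic
    scan generator with known ground truth supports end-to-end testing, and a
    command-line dispatcher ties the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
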