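Package: repliccs
Title: Cell-Cycle Sorting of Replication-Foci Images and Image
    Cross-Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sorts single nuclei into cell-cycle groups (G1/G2, Early-S,
    Middle-S, Late-S) from a single optical section of a replication-foci
    (EdU) image using pixel-density and pixel-intensity thresholds, and
    quantifies per-nucleus colocalization between two fluorescence channels
    (e.g. replication versus transcription foci) by image cross-correlation
    spectroscopy (ICCS): masked FFT spatial auto- and cross-correlation,
    radial Gaussian amplitude fits, and the colocalized fractions f1/f2.
    Includes nucleus segmentation and count-mask generation, rolling-ball
    background subtraction, foci binarization, a synthetic fluorescence
    scene generator with ground-truth colocalization for validation, and
    batch reporting with Mann-Whitney group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
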