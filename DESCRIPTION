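Package: peakforge
Title: Multi-Algorithm GC-MS Peak Picking with SVM Peak-Quality Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A self-contained workflow for gas chromatography-mass
    spectrometry (GC-MS) metabolomics peak detection. Built-in matched-filter
    and continuous wavelet transform peak pickers are run over user-declared
    parameter grids; every detected peak is classified into one of seven
    quality classes by a support vector machine trained on labelled peak
    windows; a class-weighted score selects optimal picker parameters by
    exhaustive grid search; per-algorithm peak sets are filtered,
    deduplicated and merged into a single high-quality peak set with
    retention-index calibration, reverse spectral-library matching, a
    cross-sample feature table and simple two-group statistics. A
    chromatogram simulator with ground truth makes the full pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ncdf4,
    mzR,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
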