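Package: fpolcyto
Title: Fluorescence Polarization Imaging Cytopathology Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of methylene-blue fluorescence polarization
    (Fpol) in confocal images of cytology specimens. Provides instrument
    polarization calibration (G-factor) from four-configuration dye-solution
    measurements, processing of co-/cross-polarized 8-bit image pairs into
    background-corrected per-pixel and per-cell Fpol values, threshold-based
    malignancy classification of single cells, and linear mixed-effects group
    analysis with least-squares means for diagnostic, histologic, and
    tumor-grade groupings. A synthetic-data module simulates calibration image
    sets, polarized cell-monolayer fields with ground truth, and hierarchical
    cell cohorts, so the full pipeline can be exercised and validated without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    lme4,
    png,
    stats,
    tiff,
    utils
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
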