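Package: stretchfield
Title: Strain Mapping and Cell Readouts for Pneumatic Cell-Stretching Videomicroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of pneumatic cell-stretching experiments
    recorded by time-lapse microscopy. Estimates membrane displacement fields
    from speckle or phase-contrast image pairs by multi-pass windowed FFT
    cross-correlation (digital image correlation), derives Green-Lagrange
    strain fields and their spatially averaged, normalized time series,
    quantifies cell-level readouts (monolayer kinematics, junctional
    fluorescence integrals, per-cell shape morphometrics with tracking), and
    models the pneumatic actuation path (set-point waveforms, valve response,
    pressure-change-rate statistics, implied strain rates). A synthetic-data
    generator produces speckle patterns, monolayer image sequences and
    pressure traces with known ground truth for validation of the full
    analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
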