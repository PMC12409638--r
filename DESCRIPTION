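Package: ramancff
Title: Raman Soft Sensors for Multi-Attribute Monitoring of Dual-Stage
    Cross-Flow Filtration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric soft sensors for in-process Raman spectroscopy during
    recovery of precipitated virus-like particles (VLPs) by dual-stage
    cross-flow filtration.  Provides attribute-specific spectral preprocessing
    pipelines (OH-band normalization, pre-cropping, adaptive smoothness
    penalized least squares (asPLS) Whittaker baseline correction,
    Savitzky-Golay smoothing, cropping, unit-variance scaling), regression
    models for the precipitant ammonium sulfate (AMS) and the VLP product
    (single-wavenumber linear regression and NIPALS PLS1 with cross-validated
    latent-variable selection and VIP-based interval selection),
    detector-saturation and defective-spectrum quality control, calibration
    transfer across exposure times, and a synthetic spectrum / diafiltration
    process generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    data.table,
    deSolve,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
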