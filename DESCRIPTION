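Package: scyf
Title: Single-Cycle Fractal Compression for ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossy compression of single-lead electrocardiogram (ECG) signals by
    single-cycle fractal coding: one representative heart cycle is stored as the
    self-similarity domain and every non-overlapping range block of the signal is
    encoded as an affine map (scale, shift, optional pairwise sample swap) of the
    most similar overlapping domain block, with thresholded recursive block
    division driven by the fractal root-mean-square (FRMS) residual. Includes a
    bit-exact '.scyf' container format, one-pass reconstruction with optional
    local-regression smoothing, compression-efficiency and distortion metrics
    (avL, CF, PRD, PRDN, MSE, SNR, MAX, STDERR, QS), a seeded synthetic ECG
    generator for end-to-end testing, CSV and WFDB input, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
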