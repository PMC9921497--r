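Package: cissadwt
Title: Ocular Artifact Removal from Single-Channel EEG via Circulant
    Singular Spectrum Analysis and Wavelet Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated removal of eye-blink (EOG) artifacts from
    single-channel electroencephalogram (EEG) recordings.  The signal is
    decomposed into frequency-ordered components by circulant singular
    spectrum analysis (CiSSA); components carrying the blink are flagged
    by joint kurtosis and energy thresholding; their low-frequency
    content is stripped with a four-level discrete wavelet transform
    (db4) by zeroing the approximation band; and the clean EEG plus an
    estimated artifact are reconstructed by the inverse transforms.
    Includes the standard evaluation metrics (RRMSE, correlation, SAR,
    alpha-band MAE), a parametric generator of contaminated synthetic
    EEG for validation, delimited-text and European Data Format (EDF)
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
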