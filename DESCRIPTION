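Package: stmtrf
Title: Spectrotemporal Modulation Encoding and Decoding of Neural Responses to Degraded Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how prior knowledge and signal quality shape
    neural representations of degraded (noise-vocoded) speech. Implements
    noise-vocoding with Greenwood-spaced channels, stimulus feature spaces
    (broadband envelope, 24-channel spectrogram, spectral derivative,
    spectrotemporal modulations, articulatory phonetic features), lagged
    ridge-regression encoding and decoding models (temporal response
    functions) with leave-one-trial-out cross-validation, banded ridge and
    single-lag decoding, permutation null distributions, repeated-measures
    inference on model accuracies, denoising source separation, schematic
    sharpened-signal versus prediction-error simulations, and a synthetic-data
    generator (parametric word-like audio plus simulated sensor responses with
    known ground truth) so the full pipeline runs without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    data.table,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
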