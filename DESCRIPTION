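Package: emgadapt
Title: Instantaneous HD-sEMG Gesture Recognition with Multi-Stream
    Adaptive Batch Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gesture recognition from instantaneous high-density
    surface electromyography (HD-sEMG) frames. Converts per-sample electrode
    grid readings to grayscale images, fits a small convolutional network with
    per-session (multi-stream) batch normalization statistics, and adapts the
    fitted network to a new recording session or subject by re-estimating the
    batch normalization statistics from unlabeled calibration data (AdaBN),
    optionally followed by supervised fine-tuning. Includes CapgMyo-layout
    record input/output, band-stop power-line filtering, spatial median
    filtering, intra-session/inter-session/inter-subject evaluation protocols
    with sliding-window majority voting, and a synthetic session-shift
    generator for end-to-end benchmarking of the adaptation step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
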