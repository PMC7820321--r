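Package: ehgdetect
Title: Automatic Uterine-Contraction Detection from Electrohysterogram Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects uterine contractions (UCs) in multichannel abdominal
    electrohysterogram (EHG) recordings using a zero-crossing-rate (ZCR)
    modulation algorithm: channel averaging, zero-phase Butterworth low-pass
    and median filtering, amplitude elevation, sliding-window ZCR,
    normalisation and gamma-power weighting, RMS envelope extraction, and
    amplitude-plus-duration thresholding. A parallel detector runs on the
    co-registered tocodynamometry (TOCO) channel. Detections are evaluated
    against maternal-perception annotations with a tolerance-window matching
    rule (sensitivity, positive predictive value), and clinical UC parameters
    (count, frequency, half-wave-width duration, inter-peak interval) are
    summarised. A seeded synthetic-recording generator with known ground
    truth makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
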