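Package: eegapen
Title: Windowed Approximate Entropy and Companion EEG Features with
    Leave-One-Participant-Out Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Extracts windowed approximate entropy, Higuchi fractal
    dimension, Burg autoregressive coefficients and Butterworth band power
    from multichannel EEG recordings, and classifies patient versus
    control cohorts with an RBF-kernel maximum-margin classifier under
    leave-one-participant-out cross-validation.  Ships a calibrated
    synthetic-EEG cohort generator with a controllable between-group
    regularity gap so the whole pipeline can be validated end to end
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
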