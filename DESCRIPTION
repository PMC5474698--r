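Package: FFRdecode
Title: Single-Trial Decoding of Vowel Identity from Frequency-Following
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decodes vowel and stimulus identity from single-trial
    frequency-following responses (FFRs). Spectra of 250-ms speech-evoked
    scalp recordings are projected onto a principal-component spectral
    feature space fitted to an independent vowel corpus, and gradient-boosted
    decision trees classify vowel or stimulus labels, evaluated with
    one-vs-all ROC/AUC, training-size sweeps and split-count feature
    importances. Includes a source-filter vowel synthesizer and an FFR
    session simulator with controllable signal-to-noise ratio so the whole
    pipeline runs and is testable without any neural recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sandwich,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
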