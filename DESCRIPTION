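Package: strokecoh
Title: Seed-Based EEG Coherence Prediction of Early Post-Stroke Motor
    Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Resting-state EEG analysis pipeline for predicting early
    post-stroke motor recovery from seed-based spectral coherence.
    Implements preprocessing of multichannel recordings (scalp-lead
    selection, common average reference, zero-phase low-pass filtering,
    epoching with linear detrending, amplitude-based artifact rejection,
    left-right lesion flipping), magnitude-squared coherence and relative
    band power estimation by epoch-averaged FFT, construction of
    ipsilesional motor-cortex (iM1) seed coherence features, an
    elastic-net/lasso solver by cyclic coordinate descent with
    leave-one-out cross-validated penalty selection, comparison models
    from corticospinal tract lesion load and baseline motor status,
    residualized coherence prediction, serial coherence-change
    statistics, and a synthetic cohort generator with analytically known
    coherence and outcome structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    RNifti,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
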