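Package: misynergy
Title: Motor-Imagery EEG Classification with a Synergy of Convolutional Branches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end decoding of four-class motor-imagery
    electroencephalography (EEG): 7-30 Hz band-pass preprocessing with
    electrooculography (EOG) channel exclusion, cue-locked trial extraction
    and overlapping sliding-window segmentation, one-vs-rest common spatial
    pattern (CSP) filtering, wavelet packet decomposition (WPD) band
    energies, and a fusion of five heterogeneous convolutional network
    branches joined by concatenation and a softmax head. Includes a
    synthetic EEG session generator emulating the BCI Competition IV-2a
    recording protocol (22 EEG + 3 EOG channels at 250 Hz, 4 classes,
    6 runs of 48 trials per class), a minimal GDF 2.x reader, grid-search
    hyperparameter tuning with stratified cross-validation, per-class
    precision/recall/F1 evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
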