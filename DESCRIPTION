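Package: eegdecode
Title: Decoding Relaxation and Mental Workload States from Dense-Array EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for binary classification of mental states
    (guided-imagery relaxation versus mental-workload tasks) from dense-array
    EEG. Provides a seeded synthetic-EEG cohort generator (1/f background plus
    band-limited rhythms projected through smooth scalp topographies on a
    256-channel geodesic montage), signal preprocessing (zero-phase 1-45 Hz
    band-pass, RANSAC-style bad-channel detection and spatial interpolation,
    analysis-window cropping), 1-second epoching with subject-grouped
    stratified k-fold and leave-one-subject-out cross-validation, four
    from-scratch neural-network classifiers (EEGNet, BiLSTM, a strided 1D CNN
    and a CNN-BiLSTM hybrid) trained with Adam on binary cross-entropy,
    per-fold evaluation metrics, and Grad-CAM attribution maps averaged per
    subject. Includes a minimal EDF (European Data Format) reader and writer
    for interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
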