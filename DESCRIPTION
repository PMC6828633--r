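Package: coadaptBCI
Title: Co-Adaptive Motor-Imagery BCI Decoding with Supervised and
    Semi-Supervised Recurrent Retraining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses co-adaptive two-class motor-imagery
    brain-computer interface (BCI) sessions. Implements the online decoding
    chain (15-band IIR filterbank, shrinkage-regularized common spatial
    patterns, log band-power features, shrinkage LDA), statistical trial
    rejection (amplitude, joint probability, kurtosis), and two recurrent
    retraining units: a fully supervised one and a semi-supervised one that
    generates artificial labels from softmax class probabilities gated by
    interquartile confidence bounds. A synthetic event-related
    desynchronization (ERD) EEG generator makes the full closed-loop
    comparison reproducible without recorded data, and evaluation helpers
    compute accuracy time-courses, adjusted-Wald chance levels, and
    Laplacian Welch power spectra.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats
Suggests:
    MASS,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
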