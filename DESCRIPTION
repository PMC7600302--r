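Package: bciability
Title: Predicting Motor-Imagery BCI Inefficiency with Wide-and-Deep
    Regression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify a subject's ability to operate a
    motor-imagery brain-computer interface from EEG. Implements two
    neurophysiological indicators -- a pre-training desynchronization
    indicator obtained by fitting a two-Gaussian-plus-hyperbolic-noise
    model to the resting power spectrum, and an initial-training
    synchronization indicator measuring the normalized distance between
    the two classes' event-related desynchronization time courses -- a
    CSP/LDA sliding-window accuracy response, and a wide-and-deep neural
    regression network that jointly extracts data-driven indicators from
    short-time moment features and regresses them on the accuracy
    response. Includes a seeded synthetic motor-imagery EEG generator
    with known latent efficiency, leave-one-out validation, and k-means
    clustering of subjects into efficiency groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    optparse,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
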