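Package: eegcae
Title: EEG Emotion Recognition with 3D Differential-Entropy Features and a
    Convolutional Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes binary valence and arousal states from multichannel EEG
    recordings. Trials are decomposed into the theta, alpha, beta and gamma
    rhythms with zero-phase Butterworth band-pass filters, summarised per
    one-second window by Gaussian differential entropy with per-trial baseline
    subtraction, and fused into 9 x 9 x n-band spatial-spectral feature cubes
    on the international 10-20 electrode grid. Cubes are classified by a
    convolutional autoencoder: a four-layer convolutional encoder feeding a
    two-layer stacked autoencoder with greedy layer-wise pretraining and a
    softmax head, trained with cross-entropy, dropout, L2 weight decay, an
    AdaDelta optimizer and an accuracy-gated learning-rate schedule. Includes
    a synthetic-data generator emulating DEAP-style recordings with
    controllable per-band class effects, portable subject serialization,
    k-fold and leave-one-out cross-validation, and the band-combination
    evaluation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
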