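Package: respaug
Title: Variational Autoencoder Augmentation for Respiratory Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying generative data augmentation of imbalanced
    respiratory-sound corpora. Provides ICBHI-format input/output, a seeded
    synthetic lung-sound corpus generator, respiratory-cycle segmentation with
    a six-second pad-or-discard rule and stratified splitting, a mel-spectrogram
    and MFCC front end with Griffin-Lim inversion, three variational
    autoencoder variants (dense, convolutional, and class-conditional) for
    synthesising minority-class spectrograms, five MFCC-based deep classifiers,
    generative-quality metrics (Frechet audio distance, normalized
    cross-correlation, dynamic-time-warped mel cepstral distortion, PCA feature
    maps), and classification evaluation with per-class metrics and two-way
    ANOVA across training sets and classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
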