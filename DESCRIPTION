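Package: speckleSense
Title: Remote Sensing of Cortical Activity from Laser Speckle Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of secondary laser-speckle video for
    remote, contactless monitoring of brain-cortex activity. Renders
    physically grounded synthetic speckle videos in which surface tilt
    produces lateral pattern shifts (far-field phase-screen model), generates
    class-conditioned micro-vibration corpora emulating a two-session,
    two-stimulus recording protocol with a signal-free control region,
    tracks speckle displacement by subpixel cross-correlation, classifies
    40-frame video chunks with a peephole convolutional LSTM trained by
    backpropagation through time, and evaluates with a confusion-matrix
    metric suite (precision, recall, F1, Cohen's kappa, ROC-AUC), temporal
    prediction aggregation and split-model ensembling, including
    within-subject, control-region and cross-subject experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
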