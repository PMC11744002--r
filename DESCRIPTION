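Package: canet
Title: ECG Beat Characterization with a BiLSTM/Attention/Separable-Convolution Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end electrocardiogram (ECG) beat-characterization
    pipeline: discrete-wavelet (Mallat) denoising for baseline-wander and
    muscle-noise removal, Gaussian smoothing, a Pan-Tompkins QRS detector
    with R-R interval (RRI) features, beat segmentation with class-balancing
    augmentation (time warping, noise injection), and CardioAttentionNet
    (CANet) -- a hybrid classifier combining a bidirectional LSTM, multi-head
    self-attention and depthwise-separable 1-D convolutions -- for the five
    AAMI beat classes (N, S, V, F, Q). Includes baseline recurrent and
    convolutional classifiers, stratified leakage-free cross-validation,
    per-class metrics with one-vs-rest ROC/AUC, gradient-times-activation
    explanation maps, and a class-conditional synthetic ECG generator that
    provides ground truth for every stage. Neural networks are implemented
    in vectorized R with analytically derived backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
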