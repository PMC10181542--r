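Package: ecmam
Title: Dual-Channel Multimodal Attention Networks for 12-Lead ECG
    Arrhythmia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-label classification of nine arrhythmia rhythm classes
    from 12-lead electrocardiograms using a dual-channel deep network that
    fuses a one-dimensional time-series branch (channel-attention bottleneck
    residual blocks) with a two-dimensional short-time-Fourier-transform
    time-frequency branch (hybrid channel plus spatial attention blocks),
    trained with a class-frequency-weighted multi-label cross-entropy.
    Includes PhysioNet/CinC-Challenge-dialect WFDB record input/output,
    wavelet and notch denoising, spectrogram construction, a class-conditional
    synthetic 12-lead ECG generator, five-fold training with model selection
    by mean F1, and per-class/macro evaluation metrics. The network layers,
    attention gates, backpropagation and Adam optimiser are implemented in
    base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
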