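Package: PainFusion
Title: Multimodal Acute Pain Assessment from Facial Video and Heart Rate
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A transformer-based framework for automatic acute-pain assessment
    that fuses facial-video embeddings with heart-rate embeddings extracted
    from single-lead ECG. Provides Pan-Tompkins QRS detection and per-second
    heart-rate extraction, a transformer-in-transformer spatial encoder over
    face-crop tiles, a perceiver-style cross-attention heart-rate encoder with
    Fourier position encoding and bicubic expansion, latent-space augmentations
    (a learned encoder-decoder, polarity/noise, and span masking), a temporal
    cross/self-attention classifier, a leave-one-subject-out training and
    evaluation harness, and a synthetic session generator emulating the heat
    pain stimulation protocol so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'PainFusion-package.R'
    'utils-nn.R'
    'AllClasses.R'
    'synthetic.R'
    'ecg.R'
    'video.R'
    'spatial.R'
    'hrencoder.R'
    'augment.R'
    'temporal.R'
    'pipeline.R'
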