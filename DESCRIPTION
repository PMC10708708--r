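Package: bcgsq
Title: Signal-Quality Assessment for Wearable Arm Ballistocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the beat-level quality of arm
    ballistocardiogram (BCG) recordings acquired together with ECG and
    PPG at 1 kHz. The pipeline band-pass filters the channels, gates
    heartbeats on ECG R waves, locates the PPG foot by the intersecting
    tangent method, labels every 448-ms BCG beat high- or low-quality by
    three J-wave rules (a candidate before the PPG foot, amplitude above
    3 mg, width below 100 ms), encodes each beat as a square grayscale
    image via recurrence plot, Gramian angular summation/difference
    field, or Markov transition field, and classifies the images with a
    zoo of convolutional networks (LeNet variants, ResNet-18,
    DenseNet-121, SqueezeNet v1.0, and a 1-D fully convolutional
    baseline) under a repeated stratified train/validation/test
    protocol. A seeded synthetic-beat generator with known ground-truth
    fiducials makes the whole pipeline testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
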