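Package: nodulegan
Title: Edge-Enhanced Adversarial Segmentation of Pulmonary Nodules in CT
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org",
           role = c("aut", "cre"))
Description: A self-contained training and inference framework for
    adversarial segmentation of pulmonary nodules on 2.5D pseudo-colour
    CT composites. The generator is a holistically-nested U-Net with
    per-depth side outputs, softmax attention fusion and inverted
    residual stem blocks; the critic is a four-layer convolutional
    network with Gaussian-kernel minibatch discrimination and weight
    clipping. Losses combine an absolute-difference adversarial term,
    self-balanced multi-level binary cross-entropy on mask and edge
    label pyramids, and Dice. Includes a seeded synthetic phantom-CT
    generator (HU-valued slices, multi-slice vessels, solid and
    ground-glass nodules) so the whole pipeline is testable on one CPU
    without external data, plus MetaImage I/O, pixel-level evaluation
    metrics and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    digest,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
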