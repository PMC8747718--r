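Package: leafcnn
Title: Compact Convolutional Networks for Plant Leaf Classification
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for plant-leaf image classification with
    compact three-block convolutional networks (N1, N2, N3) and an
    AlexNet-shaped reference. Provides two seeded image-augmentation
    amalgamations (noise/blur/affine and fixed rotations/flips/color),
    class-per-folder dataset loading with stratified train/test splitting,
    from-scratch network construction and SGD training, macro
    precision/recall/F1 evaluation from confusion matrices, trainable
    parameter and model-size accounting, balanced two-way analysis of
    variance with replication over performance parameters, and a seeded
    procedural generator of leaf-like labeled images so the full pipeline is
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
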