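Package: fruitpoint
Title: Anchor-Free Center-Point Fruit Detection with Double Prediction
    Layers and Expanded Sample Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully self-contained implementation of an
    anchor-free center-point fruit detector for orchard phenotyping and
    automatic label generation. Objects are localized as peaks of a
    Gaussian-encoded center heatmap; a deep-to-shallow iterative fusion
    neck emits two prediction layers (2x and 4x downsampling) so small
    fruits and ordinary fruits are handled at different resolutions, and
    the heatmap branch is supervised with an expanded positive-sample
    allocation under a continuous-label loss. Includes readers and
    writers for COCO JSON and Pascal VOC XML annotations, a seeded
    synthetic orchard-scene generator emulating foreground (scale) and
    background domain gaps, a pure-R/C++ training loop with the Adam
    optimizer, heatmap decoding to scored boxes, pseudo-label export,
    precision/recall/F1/AP evaluation at the balance point, and an
    ablation harness over the double-prediction-layer and
    sample-allocation components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
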