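Package: leafpad
Title: Diffusion-Augmented Parallel-Attention Transformer Pipeline for Leaf Disease Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for plant-leaf disease classification from RGB
    imagery: classical image enhancement (histogram equalization, contrast
    stretching, median and Gaussian filtering), CutOut/CutMix/Mosaic
    augmentation with soft-label bookkeeping, a denoising-diffusion generator
    with a convolutional noise-prediction network, a parallel-attention
    Transformer classifier with a reconstruction head, a composite
    classification/reconstruction/adversarial training objective, stratified
    splitting and k-fold evaluation with multiclass metrics, and a seeded
    class-conditional synthetic leaf-image generator so the whole pipeline is
    exercisable without field data. All network forward and backward passes
    are implemented in vectorized base R.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    EBImage,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
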