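Package: ressat
Title: Spatial Gene Expression Prediction from Histology with Residual
    Networks and Spot Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts spot-level spatial gene expression from H&E-stained
    histology image patches. A convolutional encoder and a refinement
    head map each patch centered on a Visium-style spot to a
    gene-expression vector; a non-parametric scaled dot-product
    self-attention module mixes predictions across spots to exploit
    spot-spot interactions, and the two branches are trained jointly
    with a dual mean-squared-error objective. Includes readers and
    writers for SpaceRanger-style spatial datasets (MatrixMarket counts,
    tissue positions, slide image), preprocessing (patch extraction,
    total-count log normalization, highly-variable-gene union,
    batch-correction hooks), per-gene Pearson correlation evaluation
    metrics, spatial visualization of predictions, and a seeded
    two-section synthetic data generator for end-to-end testing of the
    train-on-one-section, test-on-the-other protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
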