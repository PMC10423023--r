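Package: csistrat
Title: Contrastive Data Stratification for Compound-Protein Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies compound-protein interaction data into keyed groups of
    congruent views (by compound, by sequence, or by reaction features such as
    RCLASS and EC number) and learns joint embeddings with contrastive multiview
    coding: a temperature-scaled cosine discriminator and an in-batch InfoNCE
    loss over graph-convolutional molecular encoders and 1D convolutional
    protein-sequence encoders, including Siamese weight-tied pair variants.
    Frozen encoders feed a multilayer-perceptron interaction predictor trained
    with ratio-weighted cross entropy. Includes negative sampling, unseen-entity
    splits, grouped ranking metrics (AP, MAP, R-precision, MAP@k, Precision@1),
    and a block-model synthetic data generator with group-correlated molecular
    and sequence motifs for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
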