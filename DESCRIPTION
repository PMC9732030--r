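Package: smmagcn
Title: Small Molecule-miRNA Association Prediction with Low-Rank
    Denoising and a Layer-Attention Graph Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts associations between small molecules (drugs) and
    microRNAs from a sparse binary association matrix together with
    integrated small-molecule and miRNA similarity matrices.  The known
    association matrix is first denoised by low-rank representation
    solved with inexact augmented Lagrange multipliers; the denoised
    matrix is then embedded in a similarity-weighted heterogeneous
    graph and scored by a graph convolutional network with a layer
    attention mechanism.  Includes ranking-based evaluation
    (global/local leave-one-out and repeated k-fold cross-validation),
    case-study ranking tools, and a seeded synthetic-data generator
    with planted block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
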