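Package: aoplse
Title: Antioxidant Protein Classification by Deep Latent-Space Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein sequences as antioxidant or non-antioxidant
    from composition of k-spaced amino acid pair (CKSAAP) features. The core
    model is a jointly trained autoencoder and classifier: an encoder maps
    the 400*(k+1)-dimensional pair-composition descriptor into a small
    latent space, a mirrored decoder reconstructs the input, and a softmax
    classifier head reads class labels off the latent code, all optimized
    together under a convex combination of reconstruction and
    cross-entropy loss. Includes FASTA input handling and sequence
    validation, the CKSAAP encoder, a suite of imbalanced-classification
    statistics (MCC, balanced accuracy, Youden's index, Cohen's kappa),
    latent-space separability diagnostics based on the generalized
    contrast-to-noise ratio (GCNR) with PCA and t-SNE projections, a
    synthetic planted-motif sequence generator for end-to-end testing, and
    ablation / repeated-trial orchestration with frozen-autoencoder
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
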