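Package: ampfeatr
Title: Feature Engineering for AMPylation Site Prediction from Peptide Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds numerical representations of fixed-length peptide windows
    for post-translational modification site classification, centred on
    AMPylation. Sequences are re-encoded under the standard 20-letter
    amino-acid alphabet or reduced alphabets (5 hydropathy groups, 7
    conformational-similarity groups); features are assembled from normalized
    monogram counts, offset co-occurrence (bigram) matrices, co-occurrence
    texture statistics (energy, entropy, homogeneity, contrast,
    dissimilarity) and skip-gram n-gram sequence embeddings. Includes a
    combinatorial feature-assembly framework with deterministic feature
    naming, stratified cross-validation of standard classifiers, exact and
    permutation-sampled Shapley-value explanations, a synthetic peptide
    dataset generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    glmnet,
    e1071,
    nnet,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
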