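Package: ligscreen
Title: Ligand-Based Virtual Screening with Multi-Representation Similarity Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A toolkit for ligand-based drug screening against a protein
    target from compound activity tables: validated SMILES ingestion and
    IC50/pIC50 normalization, Morgan circular fingerprints with
    physicochemical descriptors and SELFIES-style token vectors, a suite
    of pIC50 regressors with cross-validated grid search and robustness
    diagnostics, a trainable attention-fusion similarity model over the
    three molecular representations with a Tanimoto baseline,
    diversity-aware candidate-library reduction and similarity screening
    with ranked hit export, K-means/SAR/maximum-common-substructure
    analytics, and a synthetic structure-activity generator that provides
    planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    methods,
    igraph,
    cluster,
    glmnet,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
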