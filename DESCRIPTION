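Package: necroclock
Title: Postmortem Interval Estimation from Skin Microbiome Succession
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the postmortem interval, expressed in accumulated
    degree days (ADD), from taxon-abundance profiles of the ear and nasal
    skin microbiome of decomposing cadavers. Provides the full analysis
    pipeline: reading and transforming lineage-tagged 16S count tables
    (taxonomic aggregation, row normalization, joint ear+nose matrices,
    programmatic feature curation), a degree-day calculator implementing
    half-day accrual with cold-storage and frozen-interval rules, Hill
    diversity profiles with an order-q scan against ADD, native k-nearest-
    neighbor, ridge and elastic-net regressors evaluated under a fixed
    80/20 split with 10-fold cross-validated grid search, univariate and
    tree-based feature ranking, and a cadaver-structured synthetic
    succession-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
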