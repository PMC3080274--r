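Package: dldacv
Title: Diagonal Discriminant Classification of Two-Colour Expression
    Arrays with Nested Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for diagnosing tumour subtypes from two-colour
    microarray gene expression profiles. Covers spot-level preprocessing
    (background correction, within-array print-tip Lowess normalization,
    replicate-CV array quality filtering), gene ranking by the ratio of
    between- to within-class sums of squares, diagonal linear discriminant
    analysis (DLDA), nested leave-one-out cross-validation with in-fold
    feature selection over a gene-number grid, multi-class and binary
    (local and one-vs-rest) classification strategies with independent
    test-set evaluation, and reporting via complete-linkage hierarchical
    clustering, heat maps, fold-change gene tables and gene-list overlaps.
    Includes a synthetic-data generator that emulates a two-batch
    lymph-node biopsy study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pheatmap,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
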