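Package: slipir
Title: Cell-Free Small RNA Quantification, Differential Expression, and
    Cancer Classification from SLiPiR-Seq Style Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale analysis pipeline for cell-free RNA (cfRNA)
    sequencing libraries in which read 1 carries the cfRNA insert followed
    by a poly-A tail, an 8-nt sample barcode, and the sequencing adapter.
    Provides a seeded synthetic-data generator (references, structured
    paired reads, negative-binomial count matrices with planted effects),
    barcode demultiplexing and adapter/poly-A trimming, construction of
    derived rsRNA/ysRNA references from zero-mismatch parent matches,
    exact-match and containment read counting, RPM normalization,
    per-sample quality control with fragment-length Gamma fits,
    negative-binomial Wald differential expression with
    Benjamini-Hochberg correction, stability feature selection (Top-N,
    Boruta-style shadow features, LASSO frequency), and repeated-partition
    classification (logistic regression, random forest, linear SVM) with
    risk scores, RNA-type combination panels, one-vs-rest multi-class
    models, and a two-step diagnosis rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    glmnet,
    randomForest,
    e1071,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fitdistrplus,
    jsonlite,
    optparse
Config/testthat/edition: 3
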