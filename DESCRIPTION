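Package: hicat
Title: Semi-Supervised Cell Type Annotation with Novel Type Discovery for scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cells in an unlabeled single-cell RNA-seq query dataset
    using a labeled reference dataset, while discovering and separately labeling
    cell types absent from the reference. A multi-resolution feature space is
    built from batch-corrected principal components, a two-dimensional UMAP
    embedding, and DBSCAN cluster memberships computed jointly on reference and
    query cells; a gradient-boosted tree classifier trained on the reference
    provides per-cell class probabilities, and a data-driven confidence
    threshold (the largest drop in pooled maximum class probabilities) decides
    per cell between the supervised label and a cluster-derived novel label.
    Includes a negative-binomial count simulator with batch effects for
    benchmarking, evaluation metrics for open-set annotation (unseen-type F1,
    Hungarian-aligned confusion matrices), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    uwot,
    xgboost,
    clue,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    mclust,
    optparse,
    harmony
Config/testthat/edition: 3
RoxygenNote: 7.3.3
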