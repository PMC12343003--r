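Package: hematree
Title: Hierarchy-Based Mapping of Leukemic Cells onto a Normal
    Hematopoietic Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a hierarchy-based single-cell reference of normal
    bone-marrow mononuclear cells from count matrices, partitions cells
    into metacell-like subclusters with a max-min seeded k-means, maps
    query (leukemic) subclusters onto the reference with a cosine-based
    likelihood (LIKE) score, infers lineage aberrations as cell-type
    proportion ratios on a curated hematopoietic differentiation tree,
    and scores bulk RNA-seq samples with per-cell-type LASSO models
    trained on subcluster centroids. Includes a negative-binomial
    synthetic cohort generator so the whole workflow can be exercised
    end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    glmnet,
    ggplot2,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
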