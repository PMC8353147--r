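Package: corromics
Title: Integrative Serum Proteome-Metabolome Correlation Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for integrative correlation analysis of paired
    serum proteomic and metabolomic abundance matrices together with clinical
    tumor markers (CEA, CA 19-9). Implements per-feature median normalization,
    minimum-value imputation, degenerate-feature filtering, all-pairs Pearson
    product-moment correlation with exact t-distribution p-values and
    Benjamini-Hochberg false discovery rate control, average-linkage (UPGMA)
    hierarchical clustering on correlation distance, correlation-network
    construction with anchor subnetworks and marker-based biomarker candidate
    selection, pathway-annotation set overlap, Cytoscape-compatible exports,
    and a synthetic paired-omics generator with planted covariance structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
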