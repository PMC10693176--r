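Package: scdrugsea
Title: Single-Cell Drug Sensitivity Prediction by Gene-Set Enrichment
    Against Pharmacogenomic Gene Rankings
Version: 0.1.0
Authors@R:
    person("scdrugsea", "developers", email = "scdrugsea@example.org",
           role = c("aut", "cre"))
Description: Predicts per-cell drug sensitivity from single-cell
    transcriptomes. Builds Genomic Profiles of Drug Sensitivity (GPDS) --
    per-drug gene rankings by Pearson correlation between bulk expression
    and drug potency (AUC or IC50) across cell lines -- then scores each
    cell's most relevant genes (gf-icf normalization, a TF-IDF-style
    scheme) against every GPDS with a weighted Kolmogorov-Smirnov
    enrichment statistic. Monte-Carlo p-values and per-drug
    Benjamini-Hochberg FDR yield a cell-by-drug response matrix, from
    which the package derives population-level sensitivity calls,
    precision-recall/ROC evaluation against viability gold standards, a
    binarized therapeutic-landscape clustering, a Fuzzy-Jaccard-Distance
    cell embedding, and Mann-Whitney differential drug-sensitivity tests
    between cell subpopulations. A seeded synthetic-data module generates
    bulk and single-cell fixtures with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    methods,
    optparse,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
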