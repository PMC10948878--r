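Package: primet
Title: Concordance Analysis of Matched Primary and Metastatic Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for comparing matched primary and
    metastatic tumor samples in urothelial carcinoma cohorts. Provides
    consensus filtering of multi-caller somatic variant calls with tumor
    mutational burden and microsatellite-instability scoring, read-depth
    copy-number analysis with circular binary segmentation and gene-level
    amplification/deletion calls, shared-versus-private mutation concordance
    statistics for patient-matched pairs, transcriptomic classification
    (nearest-centroid consensus molecular subtypes, k-medoids T-cell
    inflammation calls, single-sample gene-set enrichment), and single-cell
    phenotyping of imaging mass cytometry cell tables (per-image
    standardization, empirical-Bayes batch correction, batch-balanced
    nearest-neighbor graphs with Leiden clustering, marker-rule
    metaclusters, and basal/luminal plasticity ratios). A synthetic-data
    layer generates every input with known ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    sva,
    vcfR,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
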