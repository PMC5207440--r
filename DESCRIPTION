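Package: claudinlow
Title: Identification of Claudin-Low Breast Cancer from Expression Profiles and Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to identify the claudin-low molecular subtype of breast
    cancer. Implements nearest-centroid molecular subtyping of expression
    compendia with standardized centroids and Spearman correlation,
    housekeeping-gene quality filtering, derivation of a claudin-low gene
    signature by empirical-Bayes moderated pairwise differential expression
    with Benjamini-Yekutieli adjustment, a surrogate immunohistochemical
    classifier built on Allred scores (luminal A / luminal B / HER2-enriched /
    basal-like / claudin-low), and cohort association and survival statistics.
    Synthetic-data generators emulate the statistical structure of microarray
    compendia and tissue-microarray cohorts so the whole pipeline is testable
    without external downloads.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
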