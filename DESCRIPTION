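Package: painmodnet
Title: Cross-Species Discovery of Pain Candidate Genes from Coexpression
    Modules, Protein Networks and Phenotype Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for prioritizing candidate pain
    response and regulation genes by integrating evidence across species:
    weighted gene coexpression network analysis (soft-thresholded adjacency,
    topological overlap, dynamic module detection and eigengene merging) of an
    expression matrix; hypergeometric enrichment of modules against a curated
    pain reference gene set; score-thresholded protein-protein interaction
    subnetworks with degree and maximum-neighborhood-component hub ranking;
    TMM-normalized negative-binomial exact-test differential expression between
    pain-model and control groups; Pearson correlation screens of gene
    expression against pain phenotypes across brain-region strain panels; and a
    four-criterion candidate shortlist with direction-consistency checks. A
    synthetic-data module generates every input with planted structure and
    ground-truth labels so that each stage and the full pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
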