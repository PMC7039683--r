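Package: enhancerscan
Title: Tissue-Specific Enhancer Discovery and Noncoding Variant
    Prioritization from Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Enhancerscan", "Developers", email = "enhancerscan@posteo.net",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for going from tissue-sorted ATAC-seq
    fragments to prioritized noncoding risk variants. Implements
    nucleosome-free-region selection and differential accessibility calls
    between cell populations, H3K27Ac-based active-enhancer annotation,
    an exact gapped k-mer support vector machine for enhancer sequence
    classification, deltaSVM variant-effect scoring with a resampling
    null and Bonferroni correction, genome tiling and percentile-bin
    enrichment, position-weight-matrix scanning with Tn5 footprint
    aggregation and allele-specific binding-site gain/loss calls, and a
    shuffle-controlled deep-homology test for noncoding elements. A
    deterministic synthetic-data generator emulates the sorted-cell
    inputs so the whole pipeline can be exercised and validated without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
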