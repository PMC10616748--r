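Package: premodmir
Title: Early-Pregnancy Preeclampsia miRNA Signatures and Disease-Module Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circulating qPCR miRNA profiles in early
    pregnancy: Ct-matrix quality control (detection cutoff, haemolysis delta-Cq,
    missingness filtering), quantile normalization, Bayesian-PCA imputation of
    nondetects, surrogate-variable adjustment, rank-product differential
    expression with permutation-based false-prediction rates, intersection of
    phenotype signatures, construction of a disease module on a protein-protein
    interaction network with coherence and centrality statistics, consensus
    miRNA-target rank aggregation onto the module, and hypergeometric
    over-representation analysis. Ships a synthetic-data generator that emulates
    the statistical structure of such a cohort with ground-truth labels for
    recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    sva,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
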