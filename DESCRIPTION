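Package: fursealpop
Title: Population Genomics of a Recolonizing Fur Seal: QC, Structure,
    ABC Demography, Outlier Scans and Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SNP-based population genomics of heavily exploited,
    rapidly recolonizing pinnipeds, exercised end-to-end on synthetic
    multi-colony data. Reads PLINK text PED/MAP and VCF genotype matrices,
    applies a missingness/MAF/Hardy-Weinberg/linkage-disequilibrium quality
    control chain, and computes diversity (Ho, He, FIS), Weir-Cockerham FST
    with Slatkin linearization, Mantel isolation-by-distance tests,
    hierarchical AMOVA and principal components. Includes a coalescent
    simulator for unlinked biallelic loci under piecewise-constant
    two-bottleneck demographic scenarios and a finite-island model,
    approximate Bayesian computation (rejection, direct and logistic model
    choice, local-linear posterior adjustment, scenario-confidence error
    rates), an FDIST-style FST-outlier scan with Benjamini-Hochberg
    q-values, and leave-one-out likelihood assignment of individuals to
    colonies and genetic clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
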