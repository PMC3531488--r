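Package: telosnp
Title: Multi-Study Association Analysis of Telomere-Biology Genes with
    Melanoma and Nevus Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for candidate-gene SNP association studies of
    telomere-biology genes and melanoma-related phenotypes across several
    case-control and family studies. Provides genotype quality control with
    an exact Hardy-Weinberg test and pairwise LD r2, per-study additive-trend
    logistic, exact conditional logistic and cluster-robust Poisson models,
    DerSimonian-Laird random-effects meta-analysis, adaptive rank truncated
    product (ARTP) gene-, group- and overall-level permutation tests sharing
    a single permutation null, and qPCR relative telomere length (T/S ratio)
    computation from standard curves. A synthetic multi-study data generator
    with LD-blocked genotypes, Mendelian families and triplicate qPCR plates
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    survival,
    metafor,
    sandwich,
    vcfR
Config/testthat/edition: 3
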