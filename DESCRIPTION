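Package: gbsconcord
Title: Concordance of Non-Destructive DNA Sampling Methods for
    Genotyping-by-Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for evaluating whether two DNA sampling
    methods (e.g. visceral swabs versus tissue biopsies of freshwater
    mussels) recover concordant patterns of genetic variation from
    genotyping-by-sequencing data. Includes a synthetic read generator with
    known truth, barcode demultiplexing with contaminant screening, de novo
    reference construction by greedy identity clustering, a simplified read
    mapper with biallelic genotype likelihoods, a seven-stage SNP filter
    cascade with a per-stage ledger, a Gibbs sampler for Bayesian admixture
    genotype probabilities with Gelman-Rubin convergence checks, and PCA
    plus symmetric Procrustes concordance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    data.table,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
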