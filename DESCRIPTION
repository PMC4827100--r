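Package: phenoreg
Title: Phenotype Similarity Regression for Rare-Disease Genotype Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian association testing between rare genotypes and
    ontology-coded (HPO-style) phenotypes. Compares a baseline logistic model
    against an alternative in which the log-odds of carrying a rare genotype
    increase with semantic similarity to a latent "characteristic phenotype",
    a small antichain of ontology terms estimated jointly with the regression
    parameters by Carlin-Chib Markov chain Monte Carlo. Includes ontology DAG
    utilities (OBO reader, minimal-set reduction, annotation-propagated
    information content), restricted asymmetric best-match Lin similarity with
    beta-CDF shape transforms, rare-variant genotype aggregation under
    dominant, recessive and high-impact dominant modes of inheritance, and a
    template-expressivity-noise phenotype simulator for power and specificity
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
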