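Package: shrinkPRS
Title: Polygenic Risk Scores from GWAS Summary Statistics with a
    Continuous Shrinkage Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Block-wise Bayesian Gibbs sampling of SNP effect sizes under a
    global-local continuous shrinkage prior, driven by GWAS summary
    statistics and a blocked linkage-disequilibrium (LD) reference panel.
    Provides summary-statistic parsing, allele harmonization and
    quality-control filtering, LD reference construction from reference
    genotype dosages, posterior SNP weight estimation with fixed or
    automatically learned global shrinkage, individual-level polygenic
    scoring, accuracy metrics for quantitative and binary traits (ordinary
    and Nagelkerke R-squared, AUC, top-decile odds ratio), cross-run weight
    concordance testing, a synthetic-data generator with known genetic
    architecture for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    optparse,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
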