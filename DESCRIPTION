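Package: ubtnet
Title: Latent Biological Traits from Correlated Phenotype Panels with
    Genomic Bayesian Network Inference
Version: 0.1.0
Authors@R:
    person("DREC", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives latent "underlying biological traits" from panels of
    correlated phenotypes via exploratory factor analysis (minimum-residual
    extraction, Horn's parallel analysis, oblimin/varimax rotation) followed
    by Bayesian confirmatory factor analysis fitted by Gibbs sampling, then
    estimates genomic breeding values for the latent traits with GBLUP
    (VanRaden genomic relationship matrix, EM-REML variance components) and
    infers the causal network among latent traits with bootstrap-averaged
    Bayesian network structure learning (Tabu search and Max-Min
    Hill-Climbing under a Gaussian BIC score). Includes a synthetic-data
    generator emulating an admixed beef-heifer phenotype and SNP panel, the
    full preprocessing cascade (Tukey outlier rule, correlation pruning with
    direct-measure priority, KMO/MSA adequacy screening), SNP quality control
    with the exact Hardy-Weinberg test, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
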