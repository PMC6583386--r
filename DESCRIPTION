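Package: summaryMR
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization analyses of
    continuous biomarker exposures and binary disease outcomes using
    published GWAS summary statistics. Provides reading, validation and
    allele harmonization of per-variant association tables; per-variant
    Wald ratio estimates; inverse-variance-weighted pooling with fixed or
    multiplicative random effects; generalized weighted regression for
    correlated instruments with an LD correlation matrix; the weighted
    median estimator with bootstrap standard errors; MR-Egger regression
    with a simulation-extrapolation (SIMEX) correction for weak-instrument
    attenuation; NOME-violation attenuation statistics; Cochran Q
    heterogeneity, influence and leave-one-out diagnostics; a
    product-of-coefficients mediation calculation; and a generator of
    synthetic two-sample summary statistics with known causal truth for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'diagnostics.R'
    'estimators.R'
    'mediation.R'
    'pipeline.R'
    'simulate.R'
    'summary-io.R'
    'utils.R'
    'weak-instrument.R'
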