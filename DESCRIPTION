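Package: eqtlpwr
Title: Power and Sample-Size Calculation for Bulk-Tissue and Single-Cell eQTL Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation-based power analysis for expression
    quantitative trait locus (eQTL) study design. Provides closed-form power
    for bulk-tissue eQTL under simple linear regression on additively coded
    genotype and under one-way unbalanced ANOVA, analytic power for
    single-cell eQTL under a random-intercept linear mixed model, and a
    simulation-based power engine for single-cell read counts under a
    zero-inflated negative binomial mixed-effects model fitted by adaptive
    Gauss-Hermite quadrature. Any one of power, sample size, effect size or
    minimum allowable minor allele frequency can be solved from the other
    three. Includes independent Monte-Carlo validators for every analytic
    engine, power-curve grid export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    statmod,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
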