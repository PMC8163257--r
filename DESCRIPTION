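Package: sexgwas
Title: Sex-Differentiated Genetic Architecture from Sex-Stratified GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and compares the common-variant genetic architecture of
    complex traits between sexes using sex-stratified genome-wide association
    study (GWAS) summary statistics. Implements LD score regression for
    sex-specific SNP-heritability (observed and liability scale) and genetic
    correlations with block-jackknife standard errors, a general z test for
    sex differences in any estimated statistic (heritabilities, genetic
    correlations, per-SNP effects), genomic block-jackknife tests for
    cross-trait sharing of sex-differentiated effects, gene-level aggregation
    of per-SNP heterogeneity with an LD-aware null, and hypergeometric
    gene-set over-representation. Ships a truth-known generator of synthetic
    sex-stratified summary statistics under a polygenic model with blockwise
    LD, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
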