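Package: bmistrat
Title: BMI-Stratified Case-Control Association, Meta-Analysis, and Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control genetic association studies in which disease
    cases are stratified by body mass index (lean, BMI < 25 kg/m2; obese,
    BMI >= 30 kg/m2) and compared against a shared, unstratified control pool.
    Provides a synthetic cohort generator with BMI-modified per-allele effects,
    per-study additive logistic association scans with imputation-quality and
    allele-frequency filters, genomic-control adjustment, inverse-variance
    fixed-effect and DerSimonian-Laird random-effects meta-analysis with
    stratum heterogeneity tests, a case-only genotype-to-BMI scan, a binomial
    sign-enrichment test of lean versus obese effect sizes, and weighted
    genetic risk scores with per-quintile odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    knitr,
    rmarkdown
Config/testthat/edition: 3
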