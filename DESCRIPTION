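Package: mireqtl
Title: miRNA-eQTL Association and Genotype-Based Cancer Risk Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links SNP genotypes to microRNA expression in paired
    tumor/non-tumor tissue and to case-control disease risk. Implements
    stratified 75th-percentile scaling normalization of array signal, a
    staged SNP-miRNA pair filtering cascade (expression prevalence,
    genotype availability, minor-allele variation, exact Hardy-Weinberg
    equilibrium), genotype-trend linear regression with bootstrap
    p-values, paired bootstrap t-tests of tumor versus non-tumor
    expression, Benjamini-Hochberg false discovery rate control, and
    genotype-class logistic regression odds ratios adjusted for
    covariates. Ships a synthetic-cohort generator emulating the
    assumed data structure (Hardy-Weinberg genotypes, additive
    log2-scale genotype effects, tumor shifts, zero-inflated signal,
    logistic case status) so the whole pipeline is testable without
    access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
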