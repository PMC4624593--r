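Package: enetrank
Title: Clinical-Genomic Association by Elastic-Net Regression with
    Bootstrap Rank Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for identifying genes, micro RNAs and proteins
    associated with clinical phenotypes in multi-platform tumor cohorts.
    Integrates copy-number calls, somatic mutation indicators, expression,
    methylation and protein (RPPA) matrices into a normalized feature space,
    encodes clinical parameters as numeric outcomes, fits an elastic-net
    regression with 10-fold cross-validation, aggregates rank-proportional
    feature scores per gene over bootstrap resamples, and tests each
    candidate post hoc with Fisher's exact or Mann-Whitney-Wilcoxon tests
    under Bonferroni correction. Includes a seeded synthetic-cohort
    generator with planted linear effects for end-to-end validation, and
    portal-style descriptive queries (alteration frequencies, per-subgroup
    profiles, two-hit stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
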