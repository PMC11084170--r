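Package: wshclock
Title: Epigenetic Age Clocks from Within-Sample Methylation Heterogeneity
Version: 0.1.0
Authors@R:
    person("wshclock", "developers", email = "wshclock@example.org",
           role = c("aut", "cre"))
Description: Tools to build and evaluate epigenetic age (eAge) clocks from
    read-level bisulfite sequencing data. Implements five within-sample
    heterogeneity (WSH) scores computed from read-level methylation calls
    (proportion of discordant reads, epipolymorphism, methylation haplotype
    load, and the fraction/quantitative fraction of discordant read pairs),
    age-association filtering of heterogeneity loci by rank correlation with
    multiple-testing adjustment, window-based average-methylation feature
    matrices from Bismark coverage files, random-forest and LASSO age
    prediction models with cross-validated hyperparameter selection,
    recursive feature elimination for minimal clock design, and a synthetic
    RRBS cohort simulator with planted age-dependent loci for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
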