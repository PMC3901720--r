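Package: phenopower
Title: Power and Sample Size for Genetic Association Studies with
    Phenotype Measurement Error
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic power, sample-size and measurement-error "cost"
    calculations for single-SNP association tests of quantitative-trait
    means and variances (vQTL tests), under an additive model with
    independent phenotype measurement error. Power is computed from the
    squared correlation between phenotype and allelic dosage via the
    non-central F distribution, and verified by Monte-Carlo simulation of
    genotypes and phenotypes with a compiled trend-test engine. Also
    estimates the measurement-error standard deviation from repeated
    phenotype measurements and computes Bland-Altman agreement summaries,
    so that data-derived error magnitudes can be fed back into the power
    calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
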