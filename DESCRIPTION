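Package: hbtrends
Title: Bayesian Hierarchical Mixture Models for Haemoglobin and Anaemia Trends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of national, regional, and global trends in population
    haemoglobin distributions and anaemia prevalence from heterogeneous survey
    data. Implements a Bayesian hierarchical model in which country-year
    haemoglobin distributions are five-component normal mixtures whose
    locations follow linear plus smooth nonlinear (second-order random walk)
    time trends at the global, regional, and national level, informed by
    covariates, with non-sampling, subnational, and age-mismatch variance
    components. Includes survey ingestion and inclusion rules, CDC altitude
    adjustment of haemoglobin, a synthetic survey generator with known ground
    truth, Markov chain Monte Carlo inference, and posterior summaries:
    anaemia prevalence and counts, population-weighted aggregation, change per
    decade, posterior trend probabilities, iron-amenable anaemia shares, and
    prevalence-halving probabilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
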