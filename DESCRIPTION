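Package: snarcpipe
Title: Cross-Cultural Analysis Pipeline for SNARC and MARC Effects
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of the statistical pipeline
    used in cross-cultural studies of spatial-numerical associations:
    trial-level reaction-time simulation for parity-judgment and
    magnitude-classification tasks, sequential outlier filtering with
    iterative +/-3 SD trimming, per-participant SNARC and MARC slope
    estimation (unstandardized and Fisher-z standardized), frequentist and
    default-prior Bayesian group inference (JZS Bayes factors, default
    correlation Bayes factors, permutation Jonckheere-Terpstra trend
    tests, Holm correction), H0-bootstrap classification of individual
    effects with prevalence contingency analyses, and scoring of a 7-item
    cultural directional preferences questionnaire.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
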