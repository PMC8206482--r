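Package: wordingsim
Title: Monte Carlo Evaluation of Wording Effects in Categorical Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-and-estimation pipeline for studying how item wording
    (keying) effects distort unidimensional categorical factor models.
    Generates 4-category ordinal questionnaire data from a known population
    factor model with balanced positively and negatively worded items and a
    continuous criterion, contaminates a fraction of respondents with
    carelessness, item-verification-difficulty, or acquiescence response
    patterns, fits substantive-only (1F) and random intercept item factor
    analysis (RIIFA) structural models by diagonally weighted least squares on
    polychoric and polyserial correlations, and scores model fit, loading
    recovery, person-score recovery and structural validity across a factorial
    design, including split-plot ANOVA effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    car,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
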