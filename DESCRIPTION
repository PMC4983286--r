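Package: ebtest
Title: Submaximal Cycle Ergometer Estimation of Maximal Oxygen Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates maximal oxygen uptake (VO2max) from the two-stage
    Ekblom-Bak submaximal cycle ergometer test. Implements the published
    sex-specific log-linear prediction equations, the original 2012 pooled
    linear equation, and an Astrand-nomogram comparator; method-comparison
    statistics (paired t, Bland-Altman limits of agreement, coefficient of
    variation, standard error of the estimate, error-versus-level Spearman
    correlation) with stratified reporting by sex, age band and fitness
    quartile; the forward-selection model-development procedure on the
    natural-log scale with interaction screening and tolerance diagnostics;
    and a reproducible synthetic-cohort simulator for end-to-end validation
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
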