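Package: raschform
Title: Rasch Item Banking, Expert-Judgement Aggregation and Developmental
    Instrument Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for constructing short caregiver-reported and long
    directly-administered instruments of early child development from a Rasch
    item bank. Aggregates multi-judge item-matching, domain and feasibility
    judgements into matching coefficients, equate groups and domain profiles;
    fits dichotomous Rasch item difficulties by conditional maximum likelihood
    and derives D-scores, development-for-age z-scores (DAZ), pass-age
    quantiles, test information and separation reliability; assembles
    difficulty-uniform, domain-balanced forms with semantic ordering,
    string-breaking, three-group partitioning and age-conditional start/stop
    rules; and evaluates assembled forms by simulated administration. A
    synthetic-data module generates item banks, judge panels and
    Rasch-conforming responses with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    igraph,
    jsonlite,
    pracma,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
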