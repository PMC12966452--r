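Package: forestscreen
Title: Random-Forest Analysis of Online Task Batteries for Adult Autism
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates case-control cohorts of adults completing an online
    battery of cognitive and perceptual tasks, and analyses such cohorts with
    repeated random-forest classification: exclusion of incomplete records,
    age- and gender-matched subsample construction, repeated forest fitting
    with best-model selection by F1 score, feature-importance significance
    testing against randomized-label null forests with Bonferroni correction,
    decision-tree feature co-occurrence analysis, partial dependence curves,
    and comparison with a screening-questionnaire threshold classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
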