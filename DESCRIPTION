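Package: sdtreat
Title: Signal Detection Theory Analysis of Yes/No Treatment Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses the accuracy and utility of yes/no treatment decisions
    by modelling each decision as an unequal-variance signal detection task
    with logistic distributions. Decision drivers (for example hearing loss
    in dB HL or a baseline tinnitus handicap score) are linked to observed
    yes/no choices through per-population Bayesian logistic regressions;
    the fitted model yields ROC and logit-ROC curves, an accuracy index,
    likelihood-ratio functions, and unbiased or expected-value-optimal
    decision criteria. Includes a single-imputation chain with two-stage
    ANOVA predictor screening, a synthetic-cohort generator with known
    ground truth and configurable missingness, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
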