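Package: commonfate
Title: Multilevel Common Fate Mediation Models for Dyadic Diary Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 1-1-1 dyadic mediation analysis under the common fate
    model. Fits two-level latent-variable structural equation models to
    intensive longitudinal (daily diary) data from couples by full-information
    maximum likelihood over a structured within/between covariance, computes
    Monte Carlo confidence intervals for indirect effects, and provides the
    descriptive machinery of diary studies (intraclass correlations,
    within/between correlations, completion rates, adherence categorization).
    Includes a calibrated synthetic-data generator that emulates a 14-day
    diary study of HIV-serodiscordant couples so the whole pipeline is
    testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
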