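Package: respstyles
Title: Distinguishing Extreme and Midpoint Response Styles with the
    Multidimensional Nominal Response Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models extreme response style (ERS) and midpoint response style
    (MRS) in Likert-type questionnaire data with a scoring-matrix adaptation
    of the multidimensional nominal response model. Provides the three
    canonical scoring matrices (no response style, bipolar ERS/MRS, separate
    ERS + MRS dimensions), a marginal maximum likelihood estimator based on
    an EM algorithm with Gauss-Hermite quadrature, AIC/BIC model selection
    including a BIC-then-AIC combined rule, a Monte-Carlo simulation-study
    driver for model classification accuracy, and a resampling design for
    applied datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    parallel,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
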