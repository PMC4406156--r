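Package: mvnmix
Title: Multivariate Poisson and Negative-Binomial Formulations of N-Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits N-mixture models for replicated count surveys using the exact
    multivariate Poisson, multivariate negative-binomial, and zero-inflated
    Poisson reformulations, which avoid the truncation bound K required by the
    classical likelihood. Provides the classical truncated likelihood with an
    automatic tail-probability rule for choosing K, sample-moment covariance
    diagnostics that predict infinite abundance estimates, closed-form
    method-of-moments estimators used as starting values for maximum
    likelihood, explicit detection of boundary (infinite-abundance) solutions,
    and a simulation engine for count-survey design studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
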