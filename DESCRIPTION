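Package: ionferm
Title: Statistical Analysis of Heavy-Ion Mutagenesis and Butyrate
    Fermentation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for heavy-ion-beam mutagenesis and
    anaerobic fermentation studies of butyrate-producing clostridia.
    Fits binomial generalized linear dose-response models of irradiation
    lethality (logit, probit and complementary log-log links) with a
    delayed-rejection adaptive-Metropolis (DRAM) sampler, posterior
    predictive deviance checks and predictive envelopes; fits logistic
    batch-growth kinetics by linearized least squares and by Bayesian
    sampling with an error-variance chain; screens mutant strain rating
    matrices by inverse-variance weighted principal component analysis
    with Hotelling's T-squared outlier ranking; filters pH time series
    with a one-dimensional Kalman filter; and summarizes batch
    fermentation performance (butyrate/acetate ratio, titres, yields,
    OD600 to dry-cell-weight conversion, MTT growth-delay survival).
    A seeded synthetic-data generator emulates every input kind so the
    full chain is testable without access to raw fermentation records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
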