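Package: pdcount
Title: Corrected Inference for Parameter-Driven Count Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression inference for autocorrelated count time series under
    the parameter-driven Poisson model, where serial dependence enters through
    a latent stationary Gaussian AR(1) process in the log mean. Provides the
    classical unbiased-correction (UB) sandwich covariance for the Poisson GLM
    estimator, the maximum significant rho correction (MSRC) that selects the
    largest significant autocorrelation estimate within the first five lags,
    moment estimators of the latent-process nuisance parameters, a Monte Carlo
    harness for type-I-error and power studies under an interrupted
    time-series design, and an intervention-evaluation pipeline with
    time-varying excess-risk estimation on daily count data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
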