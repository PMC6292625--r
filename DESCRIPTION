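Package: famap
Title: Mapping Household Food Availability by Inflated-Beta Regression
    Kriging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a stepwise procedure for mapping household food
    availability (FA, kcal per male adult equivalent per day) and the
    contributions of livelihood activities from geo-referenced household
    survey data. Computes the FA indicator and contribution shares from
    survey tables, fits multiple linear regression (log-FA) and
    zero-and-one-inflated beta regression (contribution shares) on
    environmental and household covariates with univariate screening,
    variance-inflation-factor filtering and stepwise AIC selection,
    quantifies residual spatial structure with method-of-moments
    variograms and nugget-sill diagnostics, interpolates normal-score
    transformed residuals by ordinary kriging (regression kriging for
    FA), and composes prediction maps with 95 percent prediction
    intervals. A synthetic-data module generates covariate rasters and
    survey-like households with known coefficients and residual spatial
    structure, so the full pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
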