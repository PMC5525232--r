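Package: equicare
Title: Income-Related Inequality in Health-Care Utilisation via Two-Part
    Hurdle Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring income-related inequality in the use of
    public and private health services across repeated cross-sectional
    health surveys. Provides a seeded synthetic survey generator, ordered
    probit harmonisation of interval-censored household income onto a
    common scale with quartile assignment, logistic imputation of the
    public/private ownership of health-service contacts from single-visit
    respondents, annualisation of recall-window contact counts with
    model-based imputation of delayed contacts, joint estimation of
    two-part hurdle models (logistic hurdle plus zero-truncated negative
    binomial frequency, NB1 dispersion, optional Gaussian random effects
    integrated by Gauss-Hermite quadrature with a penalised-complexity
    style penalty), and descriptive quartile-by-wave utilisation tables
    with rank-sum and exact tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    rlang,
    readr,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
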