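Package: hazglm
Title: Flexible Parametric Hazard Modelling via Life-Table GLMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for parametric modelling and extrapolation of hazard
    functions from time-to-event data within the generalized linear model
    framework. Individual-level records are restructured into life tables
    with actuarially adjusted at-risk exposure, on which standard survival
    models (exponential, Gompertz, Weibull, log-logistic, lognormal) are
    fitted as GLMs, alongside richer parametric hazards (gamma, generalized
    gamma, generalized F), fractional polynomials with closed-test order
    selection, restricted cubic splines with AIC knot selection, penalized
    generalized additive hazards with effective degrees of freedom,
    interval-level Gaussian frailty, and Poisson dynamic survival models
    (local level, local level with drift, local trend) estimated by
    one-step-ahead forecast error. Includes model comparison by AIC,
    data-splitting extrapolation error, life expectancy, seeded
    time-to-event simulation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    flexsurv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    splines,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
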