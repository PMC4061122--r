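Package: mgamtemp
Title: Mixed Generalized Additive Models for Temperature-Driven Daily Event Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Poisson generalized additive models with natural-spline
    smooths of a distributed-lag weighted mean temperature, day-of-week
    effects and a smooth time trend, optionally extended with an
    autoregressive random effect on the log scale (a "mixed GAM") estimated
    by maximum partial likelihood.  The three-day lag weights of the
    temperature exposure are estimated jointly with the regression
    coefficients.  Includes the model-selection procedures used in
    environmental time-series epidemiology (seasonality-invariance choice of
    the time-trend degrees of freedom, AIC choice of the exposure-spline
    degrees of freedom, residual ACF/PACF choice of the autoregressive
    order), residual diagnostics, piecewise-slope and risk-ratio summaries
    of the exposure-response curve, and a synthetic daily count/temperature
    generator for validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
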