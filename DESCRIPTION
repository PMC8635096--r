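Package: placeboMBMA
Title: Model-Based Meta-Analysis of the Placebo Response in Primary
    Sjogren's Syndrome Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits an Emax time-course nonlinear mixed-effects model to
    trial-level change-from-baseline ESSDAI scores pooled across
    placebo arms, with sample-size-weighted residual error and
    inter-trial random effects. Provides stepwise covariate selection
    on the objective function value, model qualification (goodness of
    fit, leave-one-out sensitivity, visual predictive checks, sampling
    importance resampling), Monte-Carlo simulation of the typical
    placebo response with confidence bands, and evaluation of external
    single-arm trials against a virtual placebo control. Includes a
    synthetic-data generator reproducing the design distributions of
    the published trial corpus so the full pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pracma,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
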