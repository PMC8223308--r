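Package: plossim
Title: Simulation Framework for Zero- and Max-Inflated Productivity Loss
    Outcomes in Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing work productivity loss
    outcomes in two-arm randomised controlled trials. Productivity loss
    over a fixed follow-up window is bounded and typically inflated both
    at zero (no loss) and at the maximum attainable loss. The package
    implements the three-category data-generating mechanism (multinomial
    logit category membership with a doubly-truncated negative binomial
    middle part), the analytic conditional treatment-effect estimand
    theta(x), five plug-in estimators (OLS, negative binomial GLM, two
    hurdle models with zero-truncated negative binomial or Gamma positive
    parts, and a multinomial-logit plus Beta three-part model), stratified
    bootstrap inference, and Monte Carlo performance measures (bias,
    coverage, power, empirical and model-based standard errors, mean
    squared error) with their Monte Carlo standard errors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
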