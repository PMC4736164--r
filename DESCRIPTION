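Package: curemonitor
Title: Event Monitoring and Analysis-Time Prediction for Trials with a
    Cure Fraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for blinded event monitoring of event-driven clinical
    trials whose population contains a non-susceptible ("cured") fraction,
    as seen with cancer immunotherapies. Fits parametric mixture cure rate
    models (exponential, Weibull, log-logistic and lognormal latency) to
    pooled right-censored snapshot data by maximum likelihood, and runs a
    Monte-Carlo procedure that resamples parameter uncertainty, extends
    at-risk patients conditionally on their observed follow-up, completes
    enrollment, and predicts the calendar time at which a prespecified
    event count is reached, together with the probability of study
    incompletion, confidence limits, and Schoenfeld power tracking.
    Includes a synthetic-trial generator (staggered accrual, mixture-cure
    event times, loss to follow-up, administrative cutoff) for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
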