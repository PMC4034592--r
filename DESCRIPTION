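Package: droplosers
Title: Estimation for Multistage Drop-the-Losers Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and selection-bias-adjusted estimation for multistage
    drop-the-losers clinical trials, in which a predetermined number of
    experimental arms is dropped at each interim analysis until a single arm
    remains for confirmatory testing. Provides the naive cumulative maximum
    likelihood estimate of the selected treatment mean, the unbiased final-stage
    estimate, two Rao-Blackwellized estimators based on truncated-normal
    conditional expectations, and a bias-corrected conditional MLE obtained by
    maximizing a selection-conditioned likelihood with a multivariate-normal
    orthant-probability penalty. Interval estimation via conditional
    nonparametric bootstrap resampling, profile likelihood, and Wald intervals,
    together with an operating-characteristics harness reporting bias, mean
    squared error, coverage, interval width, tail proportions and the power to
    select the truly best treatment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
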