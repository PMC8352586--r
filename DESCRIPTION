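Package: tdvmotive
Title: Temporally Discounted Value Models of Motivation and Striatal Coding
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cued instrumental delayed-reward tasks in
    which the error rate indexes motivation. Implements hyperbolic and
    exponential temporal-discounting error-rate models with an exponential
    satiation factor over normalized cumulative reward, least-squares model
    fitting with multi-start optimisation, leave-one-out cross-validated
    model comparison, a sliding-window chi-square detector for event-locked
    spike responses, regression-based classification of discounted-value
    coding neurons via standardized partial regression coefficients,
    time-resolved effect-size curves, a session-normalized bootstrap test
    for deviation of error-rate patterns from the discounting model, and a
    seeded synthetic-data generator (task sessions and inhomogeneous
    Poisson spike trains) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
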