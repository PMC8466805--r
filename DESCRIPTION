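Package: hetfx
Title: Heterogeneous Treatment Effect Estimation with Matching and Honest Causal Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating heterogeneous effects of a binary policy
    treatment (health-insurance enrollment) on child anthropometric outcomes.
    Provides a synthetic cohort generator with confounded enrollment and known
    potential outcomes, descriptive group comparisons, propensity-score
    matching estimators of the average treatment effect on the treated
    (nearest-neighbor and kernel matching with bootstrap standard errors and
    balance diagnostics), and a from-scratch honest causal forest with
    R-learner orthogonalization for conditional average treatment effects,
    variable-importance screening, subgroup effects, and heterogeneity
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
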