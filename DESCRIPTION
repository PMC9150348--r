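Package: expandrr
Title: Adjusted Risk Ratios by Expanded-Data (Doubling-of-Cases) Logistic Regression
Version: 0.1.0
Authors@R: person("Maintainer", "expandrr", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates adjusted risk ratios from cohort, cross-sectional and
    case-control data by the doubling-of-cases device: each case contributes a
    second record recoded as a non-case, after which ordinary (or
    sampling-weighted) logistic regression of the expanded data estimates
    log relative risks. Provides the robust sandwich standard error that
    corrects for the artificial duplication, inverse-probability sampling
    weights for case-control samples with or without frequency matching,
    crude and Mantel-Haenszel tabular estimators, comparison estimators
    (naive logistic, constrained log-binomial, Poisson with robust SE),
    and a Monte-Carlo harness for coverage/power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
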