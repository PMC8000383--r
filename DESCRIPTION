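Package: dmplane
Title: Decision-Making Plane Analysis for Healthcare Resource Reallocation
    under Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for appraising healthcare resource reallocation decisions
    on the decision-making plane (DMP). Implements the reallocation decision
    rule that compares the resources released by cancelling an existing
    program with the resources required by a new program, propagates
    uncertainty in program costs and effects to net outcomes by correlated
    bivariate-normal Monte-Carlo simulation and by closed-form moments with
    analytic orthant probabilities, quantifies the change in portfolio risk
    with the quartile coefficient of dispersion, and values uncertain net
    outcomes with quadrant-specific gain and loss functions whose exponents
    encode risk aversion and the change in portfolio risk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
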