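Package: panelcausal
Title: Causal Effect Estimation for Controlled Pre-Post Panel Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of the average treatment effect on the treated (ATT)
    for balanced pre-post panel designs with block treatment adoption:
    two-way fixed-effects difference-in-differences with cluster-robust
    inference, the synthetic control method with simplex-constrained donor
    weights and placebo inference, interactive fixed effects estimated by
    iterative principal components with cross-validated factor-count
    selection, and the generalized synthetic control method with
    parametric-bootstrap inference. Includes a Monte Carlo simulation
    harness that benchmarks the four estimators under parallel and
    nonparallel trends, homogeneous and heterogeneous effects, convex-hull
    violations, and differential post-intervention shocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pracma,
    withr
Config/testthat/edition: 3
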