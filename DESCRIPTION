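Package: swimmaze
Title: Individual-Based Analysis of Larval Fish Swim-Maze Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for individual-based behavioral analysis of larval and
    juvenile fish in swim-maze assays. Converts zone-labelled swim tracks
    into visit sequences and per-session kinematic metrics for six arena
    types (sociability, slalom, swimming plus-maze, show jump, open tank,
    Y-maze); computes population-scaled endpoints (mean transition latency,
    anxiety score, zone preference); classifies Y-maze exploratory actions
    (alternations, direct and indirect revisits) with a sliding window;
    quantifies behavioral consistency via ANOVA-based repeatability with
    parametric-bootstrap confidence intervals and single- versus
    summary-measure inter-test correlations; decides distribution modality
    by univariate Gaussian-mixture fitting with BIC model selection; and
    summarises group contrasts as standardized effect sizes. A seeded
    synthetic-behavior generator (continuous-time Markov zone transitions
    with subject-level random effects, mixture populations and
    parameterized Y-maze choice policies) supports calibration and testing.
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
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    lme4
Config/testthat/edition: 3
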