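Package: cfopt
Title: Active-Learning Optimization of Cell-Free Biosynthesis Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for optimizing multi-factor cell-free biosynthesis
    systems by sequential design of experiments: Plackett-Burman two-level
    screening with first-order coded-model regression, steepest-ascent
    response-surface pathing, a seven-family surrogate-regression zoo with
    nested cross-validation and three ensemble fusions (stacking, simple
    averaging, non-negative least squares), upper-confidence-bound batch
    proposal for Bayesian optimization, Monte-Carlo and exact Shapley
    feature attribution, and a closed active-learning loop. A configurable
    synthetic yield landscape stands in for the wet lab so the entire loop
    can be exercised and tested end to end. Ships the 13-factor screening,
    20-run design and 5-trial ascent tables of a liquiritigenin cell-free
    production study as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    ranger,
    e1071,
    nnet,
    xgboost,
    kernlab,
    lhs
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
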