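Package: relaxcq
Title: Inertial Relaxed CQ Algorithms for Split Feasibility Problems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projection algorithms for the split feasibility problem (SFP)
    in finite-dimensional Hilbert spaces: Byrne's CQ iteration, the
    inertial relaxed CQ method of Dang et al., the inertial generalized
    relaxed CQ (IGRCQ) method of Wang and Yu, and an inertial modified
    relaxed CQ Mann algorithm (IMRCQM) combining inertial extrapolation,
    generalized half-space relaxations and Mann averaging.  Constraint
    sets are described by convex level-set functions with subgradient
    oracles; per-iteration relaxations are half-spaces or balls with
    closed-form projections.  Includes an extreme learning machine whose
    output weights are trained as a norm-ball-constrained least-squares
    SFP for binary classification of tabular clinical data (the UCI
    mammographic-mass CSV dialect), synthetic generators for feasible SFP
    instances and labelled feature tables, confusion-matrix metrics,
    binary cross-entropy, stratified k-fold cross-validation, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
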