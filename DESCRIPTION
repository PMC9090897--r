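Package: ddmatch
Title: Drift-Diffusion Analysis of Self-Prioritization in Shape-Label
    Matching Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Response-coded Wiener diffusion modelling of two-choice
    shape-label matching data under stimulus-frequency manipulations.
    Provides the first-passage-time likelihood with inter-trial
    variabilities in drift rate, starting point and non-decision time, a
    trial-level simulator emulating equivalent, confirmatory and
    dis-confirmatory matching-task designs, declarative model ladders
    mapping design factors (and trial number) to free parameters,
    hierarchical Bayesian estimation by adaptive Metropolis-within-Gibbs,
    DIC model comparison, directional posterior probability tests, and
    parameter-recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
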