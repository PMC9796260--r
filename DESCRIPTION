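Package: urnings
Title: Multidimensional Urnings Rating System for Adaptive Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Urn-based rating system that tracks multiple learner abilities
    and item difficulties on-the-fly in adaptive learning systems. Implements
    the two-step multidimensional Urnings update with integer item weights,
    a Metropolis correction for adaptive item selection, paired-update
    anchoring of reference item subsets, item-fit diagnostics based on the
    invariant-distribution identity, Bayesian estimation of the population
    ability distribution and of individual abilities from the urn
    configurations, and a simulation harness for stationary and dynamically
    changing ability scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, Rcpp, MASS
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, yaml, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
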