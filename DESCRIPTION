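Package: thiamalloc
Title: Optimal Thiamine Allocation Between Muscles and Gonads in Salmonids
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: State-dependent life-history model of thiamine (vitamin B1)
    allocation between somatic and reproductive tissues in female salmonids.
    Computes fitness-maximizing allocation policies by backward induction
    (stochastic dynamic programming) over a discretized tissue-concentration
    state space, simulates populations of females following the optimal policy
    under stochastic daily thiamine input, and analyses the resulting daily
    gonad-to-muscle concentration regressions and Spearman rank correlations
    that serve as early-warning indicators of thiamine limitation. Includes
    concentration-dependent renal excretion kinetics (sigmoid
    reabsorption/secretion, reabsorption plus passive transport, and linear
    variants) and a synthetic tissue-measurement generator emulating
    two-system (thiamine-limited vs. replete) salmon sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
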