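Package: npecircuit
Title: Learning Negative Prediction-Error Circuits by Balancing Excitation
    and Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-based model of a layer 2/3 visual-cortex microcircuit in
    which negative prediction-error (nPE) neurons emerge through inhibitory
    synaptic plasticity. Two-compartment pyramidal cells with a dendritic
    calcium nonlinearity interact with parvalbumin- (PV), somatostatin-
    (SOM) and vasoactive-intestinal-peptide-expressing (VIP) interneurons.
    The package provides random network construction with fixed in-degrees
    and size-invariant weight scaling, sensorimotor stimulation protocols
    (feedback, mismatch, playback), four inhibitory plasticity rule
    variants including a backpropagation-of-error approximation and its
    biologically plausible local counterparts, analytic excitation-
    inhibition balance constraints with a linear steady-state oracle,
    response classification into prediction-error types, current
    decompositions, and simulated optogenetic perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
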