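Package: tempoSel
Title: Detecting Short-Term Balancing Selection from Temporal Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based detection of recent balancing selection
    (overdominance) from serially sampled haplotype data. Provides a
    forward-in-time diploid Wright-Fisher simulator with heterozygote
    advantage, recombination, infinite-sites mutation, piecewise demography,
    parameter rescaling and ancient-DNA-like serial sampling; a
    frequency-sorting encoder that turns temporal haplotype samples into
    fixed-shape network inputs; a two-branch residual convolutional
    classifier over present-day and stacked ancient haplotype matrices; and
    a repeated-training evaluation protocol reporting confusion matrices,
    accuracy confidence intervals and single-branch ablations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
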