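Package: mplexnet
Title: Structure-Function Multiplex Brain Network Analysis
Version: 0.1.0
Authors@R:
    person("MPlexNet", "Developers", email = "mplexnet@example.org",
           role = c("aut", "cre"))
Description: Builds binarized maximum-spanning-tree backbones of structural
    (diffusion MRI) and functional (resting-state fMRI) brain connectivity
    matrices, couples them into a two-layer multiplex network with unit
    interlayer links, and computes multilayer eigenvector centrality and
    eccentricity per subject. Includes frontoparietal-network summaries,
    hierarchical block regression with R-squared-change F tests,
    collinearity diagnostics, leave-site-out cross-validation with Levene's
    homogeneity test, and a synthetic multi-site cohort generator with a
    planted cognition effect for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
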