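Package: efemin
Title: Expected Float Entropy Minimisation for Multivariate Categorical Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns the weighted relations (between nodes, and between
    repertoire states) that a multivariate categorical system defines, by
    minimising the expected float entropy of its observed states. Provides
    the float-entropy machinery over the full enumerated state space with a
    fast C++ engine, coordinate-bisection optimisation with optional
    symmetry tying on spatial grids, Monte-Carlo null histograms of the
    expected float entropy, minimum-float-entropy completion of partially
    observed states with mode and uniform-guessing baselines, a greedy
    partition of the state space that recasts the objective as a
    conditional Shannon entropy, multi-relational float entropy over
    derived tuple nodes, and a generator of spatially correlated posterised
    synthetic data emulating grid-sampled greyscale image patches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Network, Software, StatisticalMethod
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'layout.R'
    'stateSpace.R'
    'relations.R'
    'typicalData.R'
    'floatEntropy.R'
    'learning.R'
    'completion.R'
    'infotheory.R'
    'multirelational.R'
    'synthetic.R'
    'images.R'
    'fixtures.R'
    'zzz.R'
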