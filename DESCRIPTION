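Package: swmnet
Title: Structural Covariance Networks of Superficial White Matter from
    Regional MTR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates and compares structural covariance networks built
    from regional magnetization transfer ratio (MTR) measurements of the
    superficial white matter. Provides a 78-node Brodmann-style atlas with
    homotopic pairing, a synthetic-cohort generator based on sparse
    Gaussian graphical models, laterality scoring with permutation GLM
    inference and step-up FDR correction, shrinkage estimation of partial
    correlation networks in the n << k regime, local false discovery rate
    (lfdr) mixture-model edge inference with Fisher-z group and hemisphere
    contrasts, lobe-level integration/segregation summaries via Gaussian
    entropy and mutual information, and density-integrated binary graph
    topology (degree, hubs, efficiency, modularity) with label-permutation
    group tests.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
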