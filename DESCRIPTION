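Package: thermograph
Title: Thermodynamics-Inspired Descriptors for Dynamic Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral descriptors for time-varying networks built from
    multivariate time series or supplied adjacency sequences. Implements
    Spectral Core Entropy (a truncated von Neumann graph entropy over the
    leading normalized-Laplacian eigenvalues), node and internal energy,
    and a temperature-like reconfiguration index T = dU/dS between
    consecutive graph windows; sliding-window Pearson graph construction
    with SSIM-based event labeling; lag-aware threshold-free detection
    evaluation (AUROC, average precision, Matthews correlation with
    permutation tests); heat-trace (NetLSD) and k-means switching
    baselines; edge-count-preserving surrogate nulls; and a
    degree-corrected stochastic block model benchmark with three
    reconfiguration regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), optparse, pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'baselines.R'
    'dcsbm.R'
    'dynamic-graph.R'
    'events.R'
    'fixtures.R'
    'io.R'
    'methods.R'
    'pipeline.R'
    'summaries.R'
    'thermo.R'
    'thermograph-package.R'
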