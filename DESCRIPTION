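Package: bpgrn
Title: Gene Regulatory Network Inference with Back-Propagation Perceptrons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reverse engineers gene regulatory networks from gene-expression
    matrices by training one single-layer sigmoid perceptron per gene with
    online back-propagation and momentum, assembling the trained weights into
    a zero-diagonal weight matrix, and thresholding incoming weight ratios to
    obtain a signed directed network. Provides the five topology statistics
    used to characterise such networks (average path length, average
    clustering coefficient, average degree, modularity, graph density), a
    Pearson relevance-network baseline, and detection of differentially
    expressed genes through a degree-difference-ratio statistic comparing a
    gene's in- and out-degrees between two condition networks. A synthetic
    expression simulator with planted regulatory structure supports
    end-to-end benchmarking, and a pipeline runner ties all stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bp-train.R'
    'bpgrn-package.R'
    'deg.R'
    'io.R'
    'network-build.R'
    'network-stats.R'
    'pipeline.R'
    'preprocess.R'
    'relevance.R'
    'simulate.R'
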