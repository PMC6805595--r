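Package: netmeth
Title: Network-Based Regularization for Case-Control Analysis of DNA Methylation
Version: 0.1.0
Authors@R: person("Methylation Networks", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Gene selection for case-control association studies with
    high-dimensional DNA methylation array data, using prior genetic-network
    knowledge. Each gene's CpG sites are collapsed to a single gene-level
    feature by one of four dimension reduction techniques (principal
    components, normalized principal components, supervised principal
    components, partial least squares). Gene-level features are then fed into
    a logistic regression penalized by a lasso term plus a graph-Laplacian
    quadratic term with sign correction, solved by pathwise cyclic coordinate
    descent. Genes are ranked by selection probabilities computed from
    balanced half-sample resampling over the whole tuning grid. The package
    also ships a Gaussian-graphical-model simulator of correlated methylation
    data, comparator methods (logistic group lasso and four per-gene tests),
    and a canonical-correlation permutation test for linked-gene
    co-methylation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    Matrix,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
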