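Package: TCRdens
Title: Distance-Preserving Autoencoder Embeddings and Local Density
    Analysis of T-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects T-cell receptor (TCR) clones, described by their CDR3
    amino-acid sequence and optionally their V gene, into a 30-dimensional
    real-valued space with a multilayer-perceptron autoencoder, optionally
    regularized to preserve pairwise Euclidean distances between the one-hot
    inputs. Local repertoire density in the embedded space is estimated with
    Gaussian kernel density estimation (cross-density between samples and
    leave-self-out self-density, with optional clone-size weighting), and
    used to compare repertoire samples, cluster them hierarchically, and
    classify single clones one-vs-all with a small fully connected head on
    the frozen encoder. Includes edit-distance and V-usage
    (Kullback-Leibler) sample similarities, descriptive embedding-space
    statistics (publicity, radius from center of mass, residue-stratified
    densities, t-SNE export), a synthetic repertoire generator for testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    ape,
    pROC,
    Rtsne
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'encoding.R'
    'autoencoder.R'
    'classifier.R'
    'synthetic.R'
    'density.R'
    'repertoire-stats.R'
    'similarity.R'
    'cli.R'
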