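Package: hicsr
Title: Resolution Enhancement of Hi-C Contact Matrices with a Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers high-resolution intra-chromosomal Hi-C contact matrices
    from low-sequencing-depth data using a three-layer valid-convolution
    network trained by stochastic gradient descent on mean squared error.
    Includes dense and sparse-triplet matrix I/O, binomial read thinning to
    simulate shallow libraries, patch extraction and merging for
    chromosome-wide enhancement, classical image-smoothing and random-forest
    baselines, distance-stratified Pearson/Spearman evaluation, virtual 4C
    track extraction, and a synthetic chromatin-contact simulator (distance
    decay, TADs, focal loops) that provides ground truth for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
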