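Package: dhlppi
Title: Deep Hash Learning for All-Against-All Protein-Protein Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein sequences into fixed-width binary hash codes
    with a Siamese one-dimensional convolutional network trained under a
    contrastive margin loss, a quantization (hash-constraint) loss and a
    bit-balance loss, and predicts protein-protein interactions by
    pigeonhole-indexed Hamming-radius search instead of exhaustive pairwise
    comparison. Includes a synthetic-data module (planted near-neighbour
    code databases and motif-driven artificial interactomes), brute-force
    search oracles, confusion-matrix evaluation and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
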