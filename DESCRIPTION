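Package: psgkm
Title: Position-Specific Gapped k-mer Prediction of RNA 5-Hydroxymethylcytosine Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA 5-hydroxymethylcytosine (5hmC) sites from fixed-length
    sequence windows centred on a candidate cytosine. Sequences are encoded as
    position-specific binary indicators of plain and gapped k-mer patterns plus
    GC-content (19,877 descriptors for 41-nt windows), reduced by mode-wise
    random-forest impurity ranking to a compact feature vector, and classified
    with L2-regularised logistic regression. Includes repeated stratified
    cross-validation with in-fold feature selection, cross-fold stable-feature
    intersection analysis, a synthetic benchmark generator with plantable
    position-specific motifs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    ranger,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
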