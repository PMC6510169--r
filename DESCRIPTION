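Package: icpred
Title: Sequence-Based Prediction of Ion Channels and Their Types
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature extraction and hierarchical classification of ion
    channel proteins from amino-acid sequence. Implements the 188-dimensional
    composition/transition/distribution (CTD) physicochemical descriptor, the
    400-dimensional k-skip-n-gram descriptor, maximum-relevance-maximum-distance
    (MRMD) feature ranking and selection, and a three-stage cascade classifier
    (ion vs. non-ion; voltage- vs. ligand-gated; K/Ca/Na/anion subtype) with
    support vector machine and random forest backends, stratified 10-fold
    cross-validation, and per-class sensitivity / overall accuracy / average
    accuracy evaluation. Includes a seeded synthetic benchmark generator with
    class-distinct residue-frequency profiles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
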