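Package: hybridreg
Title: Hybrid-Supervised Deformable Registration of Brain CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable intersubject registration of brain CT volumes by a
    hybrid-supervised convolutional network. A deformation-field simulator
    draws multiscale affine and elastic fields (with a configurable fraction
    of large deformations) to manufacture gold-standard supervision; a
    dilated encoder-decoder predicts dense displacement fields; training
    combines a supervised field-deviation loss with self-supervised local
    squared normalized cross-correlation image similarity. Includes synthetic
    skull-bearing CT phantoms with territory labels and landmarks,
    preprocessing (skull stripping, Z-score normalization), and an
    evaluation battery (landmark endpoint error, normalized mutual
    information, territory Dice, paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
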