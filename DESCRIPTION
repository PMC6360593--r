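Package: riemi
Title: Riemannian Geometry Classification of Multiclass Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of multiclass motor-imagery EEG trials on the
    Riemannian manifold of symmetric positive-definite spatial covariance
    matrices. Implements the affine-invariant geometry (distance, Karcher
    mean, exponential and logarithmic maps, tangent-space vectorization),
    minimum-distance-to-Riemannian-mean classifiers with Fisher geodesic
    filtering (MDRM, FGMDRM), a subject-specific decision tree that chains
    one-vs-rest nodes ordered by cross-validated separability, and a
    tangent-space feature stack combining semi-supervised joint mutual
    information ranking with polynomial-kernel generalized discriminant
    analysis (SJGDA). A synthetic generator of covariance-coded EEG-like
    trials makes the whole stack testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
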