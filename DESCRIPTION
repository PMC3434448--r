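Package: cortexlayout
Title: Functional Cortical Layout from Prewhitened Resting-State Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives a functional layout of cortical areas from resting-state
    voxel time series. Raw series are prewhitened to white-noise innovations
    with ARIMA models (with Ljung-Box and Durbin-Watson diagnostics), voxel
    pairwise correlations are pooled through the Fisher z transform into a
    subject-averaged area proximity matrix, a UPGMA dendrogram is built on
    squared Euclidean profile distances, the serial leaf order is regressed on
    stereotaxic coordinates, and Cherniak's compact-placement postulates
    (adjacency rule, size law, metamodule grouping) are tested with seeded
    permutation nulls. A synthetic multi-subject generator with known
    spatial-connectivity ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
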