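Package: pettex
Title: Kinetic and Textural Quantification of Dynamic TSPO PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dynamic brain PET two ways and compares the results as
    classifiers. The kinetic route extracts a pseudo-reference region by
    supervised cluster analysis over four kinetic tissue classes, computes
    voxelwise distribution volume ratio (DVR) images with the Logan reference
    graphical method, and reduces them to region-of-interest means. The
    textural route sums a late acquisition window, quantizes the whole-brain
    volume, accumulates a pooled 3D gray-level co-occurrence matrix and
    computes the fourteen classical Haralick features. Both feature families
    feed a common selection stage (correlation filter, penalised-logistic
    ranking, sample-to-feature cap), leave-one-out cross-validated linear
    support vector machines, per-feature group statistics with a
    Shapiro-Wilk gate, and a Cochran's Q comparison of the paired
    classifiers. A synthetic dynamic-PET cohort generator built on the
    simplified reference tissue model provides fully reproducible test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
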