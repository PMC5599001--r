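Package: bactex
Title: Fisher Vector Texture Classification of Bacterial Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of Gram-stained bacterial micrographs by orderless
    texture pooling. Extracts dense SIFT descriptors (and pluggable deep
    local-descriptor fields), pools them into Fisher Vectors over a
    diagonal-covariance Gaussian mixture model, and classifies with one-vs-all
    linear support vector machines, Bayes-optimized kernel SVMs, or boosted
    decision trees. Includes repeated equal-split evaluation, a class-count
    scalability study with linear extrapolation, and a seeded synthetic
    micrograph-texture generator so the whole pipeline can be exercised
    without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    rpart,
    lhs,
    png,
    tiff,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    EBImage,
    optparse
Config/testthat/edition: 3
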