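Package: mtrptex
Title: Texture-Feature Discrimination of Myofascial Trigger Points in
    B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating active myofascial trigger points,
    latent trigger points, and healthy muscle in B-mode ultrasound images
    of the upper trapezius using texture features.  Implements four
    feature-extraction approaches (local binary patterns, a 40-filter
    Gabor bank, the composite SEGL chain with 8-direction gray-level
    co-occurrence matrices and Canny edges, and seven statistical
    features), leave-one-site-out evaluation of seven classifier families
    with micro-averaged performance metrics, majority-vote ensembling,
    single-feature and leave-one-feature-out importance analyses, and
    one-way ANOVA group comparisons.  Includes a synthetic speckle-phantom
    cohort generator with full ground truth that emulates the sweep
    acquisition design the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class,
    rpart,
    randomForest,
    glmnet,
    e1071,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
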