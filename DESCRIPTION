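Package: segbo
Title: Interactive Bayesian Optimisation of Image Segmentation Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Human-in-the-loop Bayesian optimisation of image-processing
    pipeline configurations. A Gaussian-process surrogate with a
    squared-exponential kernel maps pipeline settings to a 1-10 quality
    score obtained from a user, from rule-based tolerance criteria on
    object measurements, or from a weighted composite of both; Expected
    Improvement selects the next configuration to evaluate until the
    user's target quality is met or an iteration budget is exhausted.
    Ships a reference two-stage (nuclei then cells) segmentation pipeline
    with adaptive local-mean thresholding and seeded propagation, a seeded
    generator of fluorescence-like cell images with per-class ground-truth
    masks, a simulated rater mapping mask IoU to ratings, and
    IoU-based benchmarking against random search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    lhs,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
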