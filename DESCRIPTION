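Package: fefclust
Title: Consensus Clustering of Visuomotor Neuron Response Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Functional categorization of frontal eye field (FEF) neurons
    recorded during memory-guided saccades. Builds spike density functions
    from task-aligned spike trains, screens unit isolation quality, runs a
    grid of 48 preprocessing pipelines (six firing-rate scalings, four
    response measurements, two distance metrics), clusters each with
    group-average agglomerative linkage, and aggregates the pipelines into a
    z-scored median composite distance matrix whose consensus categories are
    selected under minimum-membership criteria. Includes the traditional
    visual/movement/visuomovement classifier, categorization-quality
    statistics (penalized ratio of variances, adjusted Rand index with
    permutation inference, signed chi-square with bootstrap z), biophysical
    spike-train metrics and Gaussian response-field fits, leave-one-out
    linear-classifier cross-validation on principal components of the
    composite matrix, and a seeded synthetic population generator with
    planted category structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    stats,
    utils,
    ape,
    yaml,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
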