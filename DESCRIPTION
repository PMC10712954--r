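Package: objstrat
Title: Computationally Informed Object-Recognition Experiments In Silico
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing visual object-recognition
    discrimination experiments with the help of a hierarchical feature model.
    Renders a parametric concavity-by-alignment object family as 100x100
    grayscale images with identity-preserving transformations (3D rotation,
    light location, size, position), fits per-sublayer PCA-standardised linear
    max-margin readouts with input-noise calibration, computes signed-distance
    classification scores for stimulus pairs, searches for pairs that
    dissociate early versus late stages of the feature hierarchy, simulates
    trial-level behaviour of rat-like and human-like observers with the
    touchscreen session structure (old trials, correction trials, random
    reward), and provides the statistical toolkit used with such designs:
    per-pair accuracy matrices with exclusion rules, exact binomial chance
    tests, per-layer correlation profiles with permutation tests, split-half
    reliability with Spearman-Brown correction, combined cross-dataset
    reliability, layer-wise multiple regression, and brightness and
    pixel-similarity predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    e1071,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
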