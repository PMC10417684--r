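Package: beetlefuse
Title: Dung Beetle Optimization with Entropy Feature Fusion for Lung CT Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-class lung computed-tomography classification
    pipeline built from a dung beetle optimizer (a four-role swarm
    metaheuristic with rolling, dancing, brood-ball, foraging and thieving
    position updates), entropy-weighted fusion of convolutional feature
    extractors, and a peephole long short-term memory classifier trained by
    mini-batch gradient descent. Ships a synthetic lung-image fixture
    generator with controllable class separability, stratified train/test
    splitting, a one-vs-rest per-class and macro-averaged evaluation stack,
    and an end-to-end orchestration layer in which the optimizer tunes the
    classifier's hyperparameters against held-out classification error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
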