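Package: listlearn
Title: Digital List-Learning Episodic-Memory Assessment Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for gamified verbal list-learning assessment of
    episodic memory in the California Verbal Learning Test (CVLT) tradition.
    Generates frequency-matched 16-item learning lists and the 44-item yes/no
    recognition list, runs a configurable administration protocol as a state
    machine over any responder, scores the full episodic-memory variable
    battery (learning slope, semantic and serial clustering against chance
    expectation, serial-position effects, interference, recognition
    discriminability and d-prime, error profiles, latencies), simulates
    behavioral cohorts across healthy, mild-cognitive-impairment and
    Alzheimer's groups, and evaluates diagnostic classification with repeated
    holdout and leave-one-out cross-validation, random-forest variable
    selection, correlation studies and paired pre/post comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    glmnet,
    ranger,
    e1071,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
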