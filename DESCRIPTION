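Package: cdrex
Title: Continuous-Time Deconvolutional ExGaussian Regression for Naturalistic Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissociating word-frequency and word-predictability effects
    in naturalistic reading. Implements continuous-time deconvolutional regression
    of timestamped word-event streams onto the location, dispersion, and skewness
    parameters of an exGaussian reading-time distribution, with by-participant
    mixed effects, seeded model ensembles, ablation-based null models, and paired
    permutation tests of out-of-sample conditional likelihood. Includes a
    generative simulator with known ground truth for parameter-recovery studies,
    n-gram surprisal predictors (unigram, and smoothed bigram and trigram),
    word-level surprisal aggregation from subtoken log-probabilities,
    scan-path, first-pass, and go-past reading measures with per-dataset filter
    protocols, and effect-curve extraction (instantaneous effects, interaction
    overlays, and delay timecourses) with ensemble uncertainty bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
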