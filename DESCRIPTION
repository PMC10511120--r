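Package: chordstab
Title: Psychoacoustic Features and Bayesian Models of Chord Stability Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how psychoacoustic properties of chords
    predict two-alternative forced-choice judgements of musical stability
    ("finishedness"). Builds dyad and triad stimulus sets under width and
    mean-pitch constraints, renders them by additive synthesis, extracts
    roughness (pairwise partial interaction kernel), harmonicity
    (harmonic-template similarity on a perceptually smoothed log-frequency
    spectrum), spectral entropy and mean pitch, screens pathological
    response blocks, and fits Bayesian multilevel logistic and Thurstone
    paired-comparison models via JAGS with directional hypothesis
    summaries (posterior probability, evidence ratio, ROPE) and
    predictor-subset comparison by Pareto-smoothed importance-sampling
    leave-one-out cross-validation. A synthetic-experiment generator with
    known ground truth supports end-to-end testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
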