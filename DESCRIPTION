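Package: gazeorient
Title: Gaze Orienting and Saccadic Arousal Analysis for Cued Face-Viewing
    Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for eye-tracking studies of social orienting in which
    gaze is cued to a facial region (eyes or mouth) and the first gaze
    shift to the other region is the outcome of interest.  Provides a
    seeded synthetic-gaze generator with known ground-truth events,
    velocity-threshold (I-VT) fixation/saccade classification,
    cubic-spline up-sampling for peak saccadic velocity recovery, the
    peak-velocity/amplitude arousal index, cued-AOI first-gaze-shift
    extraction with trial and participant inclusion rules, and
    random-intercept linear mixed-model comparisons with likelihood-ratio
    tests, BIC-based Bayes factors, Nakagawa-Schielzeth marginal f2
    effect sizes, Benjamini-Hochberg correction, and simulation-based
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
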