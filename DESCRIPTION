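Package: cardiothought
Title: Event-Locked Cardiac Reactivity, Interoceptive Accuracy, and
    Probe-Caught Thought-State Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studies relating interoceptive accuracy
    to thought shifting under covert cardiac perturbation. Scores the
    heartbeat counting task and time estimation task, extracts RR intervals
    from pulse apex times, detects mean/variance change points in
    event-locked RR windows with an exact penalized segmentation, computes
    the heart-rate change-rate statistic, codes probe-caught thought reports
    into transition/continuation/contemplation/consistency indicators,
    derives frequency-domain heart-rate variability (VLF/LF/HF, LF/HF), and
    fits Bayesian hierarchical Gaussian and Poisson regressions with
    participant random intercepts via JAGS. Includes a synthetic-cohort
    generator that plants known effects (vibration-locked RR steps, a
    score-by-vibration interaction on self-referential thought continuation)
    for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rjags,
    coda,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
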