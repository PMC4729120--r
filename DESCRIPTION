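Package: sparrowtrack
Title: Automated Radiotelemetry Tracking of Age-Structured Songbird Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes coded-tag detections from an automated VHF receiver
    array into validated detection runs, migratory tracks, and behavioural
    events (flights, stopovers, reverse migrations), and compares adult and
    juvenile migration statistically.  Implements burst-interval detection
    filtering, rhumb-line geodesy, circular statistics (Watson-Williams and
    Watson two-sample U2 tests), Fisher's exact test from the hypergeometric
    distribution, Gaussian and Poisson two-group generalized linear fits, and
    a random-intercept mixed model for stopover durations.  Ships a cohort
    simulator that generates tag deployments, ground-truth tracks and the
    detection logs an imperfect receiver array would record, so the whole
    pipeline can be exercised end to end without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
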