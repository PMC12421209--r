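Package: jitaisim
Title: Simulation and Analysis of Control-Chart-Triggered Just-in-Time
    Adaptive Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and evaluating just-in-time adaptive
    interventions (JITAIs) triggered from ecological momentary assessment
    (EMA) streams. Provides a synthetic EMA cohort generator with
    person-specific autoregressive distress dynamics, missingness and
    careless responding; personalized Shewhart individuals control charts
    with moving-range sigma estimation; a four-condition microrandomized
    trigger engine (fixed cutoff, statistical process control, momentary
    support need, no intervention) with a daily delivery cap and
    omitted-control bookkeeping; and feasibility and proximal-outcome
    analyses (compliance, careless-response rates, variance decompositions,
    Welch t contrasts with Cohen's d, and lagged change-score analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
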