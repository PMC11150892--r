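Package: careflow
Title: Process Mining of Stepped-Care Pathways from Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing mental-health care pathways from
    time-stamped electronic-health-record event logs. Provides an event-log
    data model with delimited-text readers and writers, repair of
    out-of-order timestamps by last-observation-carried-forward with a full
    adjustment report, declarative event-log abstraction (stage renaming,
    subprocess collapsing, administrative-stage exclusion, variant-coverage
    filtering), directly-follows process maps annotated with patient flows,
    branching probabilities, median waits and a bottleneck indicator,
    common-route (trace variant) analysis with per-route waiting-time and
    recovery summaries, and cohort-level service metrics (treatment
    completion, recovery via caseness, missed appointments). A seeded
    discrete-event generator of synthetic stepped-care event logs with known
    ground truth supports testing and method development without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2,
    withr
Config/testthat/edition: 3
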