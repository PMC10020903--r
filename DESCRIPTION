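Package: alertmetrics
Title: EHR Activity Metrics for Monitoring Clinical Decision Support Alerts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs clinical decision support (CDS) alert episodes from
    electronic health record (EHR) event logs and computes completion and
    burden metrics for interruptive and noninterruptive Best Practice
    Advisory alerts: encounter-level alert completion rates under several
    completion definitions, alert firing rates (firings per completion), and
    per-encounter handling times, with temporal (3-month window), clinic,
    encounter-relevance and demographic stratification. Includes a stochastic
    event-log simulator with a per-encounter ground-truth ledger and a
    deterministic calibration expander that realizes aggregate monitoring
    counts as an event-level fixture, so the whole pipeline is testable
    without access to real EHR data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
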