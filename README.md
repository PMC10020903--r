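# alertmetrics

EHR activity metrics for monitoring clinical decision support (CDS) alerts.

Quality-improvement programs increasingly deploy Best Practice Advisory
(BPA) alerts in the EHR — here, a tobacco-cessation pair: a **screening
alert** prompting staff to complete a smoking assessment (fired for current
or unknown-status smokers) and a conditional **support alert** prompting the
provider to discuss cessation and referral (fired only after a positive,
documented screen). Evaluating such alerts usually relies on surveys or
direct observation; `alertmetrics` instead computes monitoring metrics
automatically from the alert activity records the EHR already keeps, for
implementation teams who need to track adoption and burden across clinics
over time.

## Metrics

From instance-level alert events the package reconstructs **alert
episodes** (all firings of one alert in one encounter, ordered in time) and
rolls them up to per-encounter outcomes, then computes:

* **Completion rate** — encounters where the prompted action was completed
  over encounters where the alert fired, under six definitions
  (acknowledged screening, documented screening, discussion, referral,
  responded-without-postponing, ready to quit), overall, per clinic, per
  3-month window from each clinic's go-live, and stratified by encounter
  relevance, sex and race.
* **Firing rate** — total firings per completion over interruptive
  episodes, `fired / completed`; the average number of interruptions needed
  to obtain one completion (undefined, and flagged as such, when nothing
  completed).
* **Handling time** — mean seconds per encounter spent completing the
  alert (over completing encounters) and postponing it (over encounters
  postponed at least once), from firing-to-response durations.
* **Two-proportion comparison** — Pearson chi-square (df 1, no continuity
  correction) between strata, e.g. relevant vs less-relevant encounter
  types.

Because real alert logs are rarely shareable, the package also ships a
**simulator** (`simulate_alerts()`) that generates event logs with the same
conditional firing logic plus a per-encounter ground-truth ledger used as a
testing oracle, and a deterministic **calibration expander**
(`expand_calibration()`) that realizes published aggregate counts as an
event-level fixture.

## Worked example

```r
library(alertmetrics)

d <- read_dataset(system.file("extdata", "toy10", package = "alertmetrics"))
#> read dataset from .../toy10: patients=10, encounters=10, clinics=2,
#>   alert_events=14, flowsheet=6
episodes <- build_episodes(d)
outcomes <- rollup_encounters(episodes, d)

completion_rate(outcomes, "ack")
#> # A tibble: 1 × 5
#>   definition numerator denominator  rate filter
#>   <chr>          <int>       <int> <dbl> <chr>
#> 1 ack                4           7 0.571 within 12 months of go-live

firing_rate(episodes, "screening")
#> # A tibble: 1 × 6
#>   alert_kind scope   fired completed  rate undefined
#>   <chr>      <chr>   <int>     <int> <dbl> <lgl>
#> 1 screening  overall     8         3  2.67 FALSE

handling_time(outcomes, "screening")
#> # A tibble: 1 × 5
#>   alert_kind mean_complete_s n_complete_encounters mean_postpone_s
#>   <chr>                <dbl>                 <int>           <dbl>
#> 1 screening             40.8                     4            27.3
```

The screening alert fired in 7 of the 10 encounters; staff acknowledged
completion in 4 (rate 0.57). Interruptive screening episodes fired 8 times
for 3 completions (2.67 firings per completion), and completing encounters
took 40.8 s of handling on average versus 27.3 s per postponing encounter.

A command-line wrapper covers the same pipeline
(`exec/alertmetrics simulate | expand | validate | metrics | report`); the
`report` subcommand flags clinics whose windowed completion rate deviates
from the pooled rate by more than a threshold (default 0.15).

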