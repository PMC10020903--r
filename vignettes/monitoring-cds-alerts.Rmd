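---
title: "Monitoring CDS alerts with EHR activity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring CDS alerts with EHR activity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alertmetrics)
```

## The monitoring problem

Electronic health record (EHR) systems record every firing of a clinical
decision support (CDS) alert and every provider response to it in an event
log. `alertmetrics` turns those logs into implementation-monitoring metrics
for a two-alert tobacco-cessation program used in cancer clinics:

* a **screening alert** reminding clinic staff to complete a smoking
  assessment, fired when the chart shows a *current smoker* or *unknown
  smoking status*, and
* a **support alert** prompting the provider to discuss cessation support
  and referral, fired only when the screening result is positive (current
  smoker) and the screener questions are documented.

Each alert has an **interruptive** modality (a pop-up when the chart is
opened that, if postponed, refires after 10 minutes or when the chart is
reopened) and a **noninterruptive** modality (a passive entry in the Best
Practice Advisory section). Monitoring asks three questions: did providers
complete the alerts (and did completion change over time or differ across
clinics); how much interruption burden did the alerts impose; and which
factors (encounter relevance, demographics) were associated with
completion.

## Data model and episode reconstruction

The event-log model has five tables — patients, encounters, clinics, alert
events, flowsheet rows — plus an *action vocabulary* mapping raw
override-reason button labels (`"Documented in Flowsheet"`, `"Defer"`, ...)
to a closed set of canonical actions. Matching is exact after trimming
whitespace and case-sensitive, because EHR button labels are fixed strings;
the mapping is user-configurable since deployments differ. Timestamps are
stored in UTC at whole-second resolution and durations as integer seconds;
if a real export carries sub-second precision it is truncated. The CSV
dialect is fixed (comma-separated, UTF-8, mandatory header, empty string =
missing) so that write-then-read is the identity; the same schemas are
accepted as JSON lines.

An **alert episode** is the set of alert instances sharing one alert id:
all firings of one alert within one encounter, from first firing to final
disposition. `build_episodes()` orders instances by firing time (ties
broken by ascending instance id, for determinism) and derives:

* `modality` — interruptive if *any* instance interrupted (chart open,
  chart reopen, timer refire). Mixed episodes are classed interruptive
  because the burden analysis targets interruptive exposure.
* `final_action` — any responding (non-defer) action outranks defers, and
  the last responding action in time wins among responders; an episode with
  only defers is a defer, one with no response at all is `no_response`.
  This matches the encounter-level reading of completion: an encounter
  counts as completed if completion happened at all.
* `completed` — the episode contains a completing action:
  acknowledgment of screening completion for the screening alert, a
  documented discussion (ready or not ready to quit) for the support alert.

`rollup_encounters()` aggregates episodes to one row per encounter in which
an alert fired, joining demographics, the clinic's go-live date and an
encounter-type **relevance map** (physician classification of whether the
encounter type is an appropriate occasion for routine tobacco screening;
the packaged map is a documented example, not an institutional standard).
Screening documentation is evaluated from the encounter's flowsheet rows —
every configured screener question answered with a non-empty value —
*regardless of which button was pressed*, so the roll-up exposes the
acknowledged-but-undocumented gap that arises when staff acknowledge
completion while a patient navigator documents (or fails to document) the
screener separately.

## Metrics

**Completion rate.** For a definition $d$ with flag set $C_d$,

$$ R_d = \frac{\#\{\text{encounters where the prompted action was completed}\}}
             {\#\{\text{encounters where the alert fired}\}} $$

with six definitions: `ack` and `documented` for the screening alert;
`discussion`, `referral`, `no_postpone` and `ready_to_quit` for the support
alert. Denominators are encounters where the respective alert fired within
the monitored 12 months.

**Firing rate.** Firings per completion over a period:
$F = \sum_i n_i \,/\, \#\{\text{completed episodes}\}$, computed over
*episodes* rather than encounters because an encounter-level ratio is
undefined (division by zero) for encounters that never complete. When no
episode in scope completed, the result carries an `undefined` flag instead
of a value. By default only interruptive episodes are counted — the burden
question is about interruptions — with `interruptive_only = FALSE`
available because event logs do not always make the intended scope
explicit. A defined rate is always $\ge 1$: every completed episode fired
at least once.

**Handling time.** Mean seconds per encounter spent completing
(over encounters where the alert was completed) and postponing (over
encounters postponed at least once). The two sets overlap by design: an
encounter deferred twice and then completed contributes to both. Within an
encounter the completing time sums the durations (response time minus
firing time) of instances with a responding non-defer action and the
postponing time sums defer-instance durations; summing counts total
provider attention. Since the within-encounter aggregation could also be
read per instance, `aggregate = "instance"` switches to total seconds over
total instances; the per-encounter sum is the default.

**Temporal and stratified views.** `completion_trend()` computes one rate
per clinic and 3-month window. Window $k$ covers the half-open
calendar-month interval $[\,\text{go-live} + 3k\text{ mo},\ \text{go-live} +
3(k{+}1)\text{ mo})$, indexed from each clinic's own go-live date; events at
or beyond 12 months are excluded from windowed outputs but retained in the
dataset. `stratify_completion()` partitions encounters by sex, race,
relevance or clinic; stratum numerators and denominators always sum to the
totals. `two_proportion_test()` compares two strata with the Pearson
chi-square on the 2×2 table (df 1, two-sided, no continuity correction —
the large-sample default; at the encounter counts involved the conclusion
is insensitive to this choice). Degenerate tables (no successes or no
failures pooled) return statistic 0 and p = 1.

Reported rounding follows the presentation conventions: completion rates to
2 decimals, firing rates to 1 decimal, handling times to integer seconds,
percentages to 1 decimal.

## The simulator

`simulate_alerts()` generates event logs with the statistical and logical
structure the analysis assumes, plus a per-encounter **ground-truth
ledger** written from the behavioral draws themselves. Because the ledger
is recorded at generation time, it is an exact oracle: every outcome flag
and metric computed by the pipeline must equal the ledger value, and the
test suite asserts this equivalence across randomly drawn configurations.

What it emulates: the conditional sequential firing logic (screening only
for current/unknown smokers; support only after a positive screen with
documented screener answers, and after the documentation time); episode
defer chains with timer refires exactly `refire_interval_s` (600 s) after a
postpone, or a simulated chart reopen; the interruptive/noninterruptive
mix; the acknowledged-but-undocumented gap via
`p_document_given_ack < 1`; lognormal handling durations per action class;
and demographics. Defer chains are capped (`max_defers`, default 20) to
bound episode length while leaving room for the long chains seen at
low-volume clinics.

Default parameters encode the monitored program's observed conditions:
`p_ack_complete = 0.55`, `p_document_given_ack = 0.58` (so documented
completion lands near 0.32), support-alert `p_support_postpone = 0.127`,
`p_discussed = 0.596`, `p_ready_given_discussed = 0.20`,
`p_referral_given_ready = 0.17`, duration means 53/52 s (screening
complete/postpone) and 50/67 s (support), and a seven-clinic layout
(two screening-only clinics) with encounter volumes scaled so that roughly
five thousand screening alerts fire in 12 months. Where the program
reported no value (the not-appropriate and no-response shares of
non-completed screening alerts, the interruptive share of episodes, the
geometric defer-chain parameters, the smoking-status mix), defaults were
chosen once at plausible clinical magnitudes — e.g. smoking prevalence 13%
with 17% unknown status, mean defer chains of 1.7 — and are documented
here rather than tuned.

What it does **not** emulate: free-text clinical content, diagnoses,
provider identity, within-day scheduling structure, non-EHR activities
(conversations, pagers), or correlation between demographics and behavior
(completion is balanced across sex and race by construction). Passing
tests therefore demonstrate the pipeline's correctness on logs with this
structure, not the clinical realism of any particular parameter.

## The calibration expander

Real event logs for the monitored program are not distributable, so
`expand_calibration()` deterministically realizes *aggregate counts* as an
event-level fixture: given per-clinic counts of fired encounters,
disposition categories, documentation, the relevance split and total
interruptive firings, it emits the minimal event log whose reconstruction
reproduces every count exactly. Extra firings beyond one per episode are
realized as defer→timer-refire chains distributed round-robin over
completing interruptive encounters; durations are fixed constants so
handling-time means are exact; encounter dates cycle over the 12 months
after go-live so all four windows are populated. Expansion involves no
randomness, so re-expanding the same counts is byte-identical.

The packaged `calibration-example.yaml` carries the program's published
aggregates. Two realization choices deserve note. First, the program
published per-clinic firing *rates* but not the underlying counts, so the
per-clinic allocations are synthetic integer pairs chosen to match every
rate at one decimal and every aggregate exactly (the file says so in its
header). Second, for the support alert the published no-postpone count
fixes how many encounters may carry defers, so its refire chains are
placed on a postponed-discussed block rather than on all completing
encounters; for the screening alert the chains sit on completing
interruptive encounters.

## Numerical and design choices

* Ties at equal firing time break by ascending instance id; all ordering
  is therefore deterministic.
* A support-alert "response without postponing" requires a response and
  *no defer anywhere in the encounter*; whether a later defer should
  disqualify a response is ambiguous in encounter-level terms, and the
  no-defer-anywhere reading is the stricter one.
* Whether published firing rates include noninterruptive firings is not
  determinable from an event log alone; the default counts interruptive
  episodes only, with an explicit switch.
* Referrals are counted only from signed orders linked to the alert — a
  deliberate undercount reproducing what the event log measures; referrals
  arranged outside the alert are invisible here.
* The modality shares of acknowledged completions reported by the program
  (84.7% + 15.4%) sum to 100.1% and are treated as independently rounded;
  the calibration realizes 2386/431 (84.70% / 15.30%).
* Undefined quantities are explicit: empty completion denominators raise a
  classed error, firing rates carry an `undefined` flag, and handling
  means are `NA` with zero-count provenance when their encounter set is
  empty.
* The asymptotic chi-square p-value diverges from exact
  (permutation/conditional) p-values at very small cell counts (tens of
  observations); the test targets the published encounter-scale
  comparisons, where the approximation is excellent.

## Problem sizes in the test suite

The packaged checks run the full pipeline on the expanded calibration
(5,121 screening and 1,074 support encounters, ~10,600 alert events),
verify pipeline/ground-truth equivalence on 20 randomly drawn small
configurations (60–600 encounters each), and recover the behavior
probabilities within three binomial standard errors on a 50,000-encounter
simulation — sizes chosen so the whole suite completes in about a minute
on a single core while keeping the binomial bounds tight.

## Limitations

EHR activity data capture provider interaction with the EHR only; the
pipeline cannot see discussions, pages or navigator workflows, and the
alert-linked referral count understates actual referrals. Alert-level
(provider-level) tracking, regression modeling of completion predictors
and live database extraction are out of scope: the inputs are exported
event-log tables, and the outputs are descriptive monitoring metrics.
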