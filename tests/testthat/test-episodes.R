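# episode reconstruction and encounter roll-up

test_that("a defer-defer-complete chain becomes one completed episode", {
  t0 <- as.POSIXct("2020-02-01 09:00:00", tz = "UTC")
  d <- tiny_dataset(events = tibble::tibble(
    alert_id = "A1", alert_instance_id = sprintf("A1-%02d", 1:3),
    alert_name = "screening", encounter_id = "E1", patient_id = "P1",
    firing_time = t0 + c(0, 640, 1290),
    response_time = t0 + c(30, 662, 1343),
    triggering_condition = c("chart_open", "timer_refire", "timer_refire"),
    subsequent_action = "acknowledge_override_warning",
    override_reason = c("Defer", "Defer", "Documented in Flowsheet"),
    signed_order = NA_character_))
  eps <- build_episodes(d)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$n_firings, 3)
  expect_true(eps$completed)
  expect_true(eps$deferred_any)
  expect_equal(eps$final_action, "ack_complete_screening")
  expect_equal(eps$modality, "interruptive")
  expect_equal(eps$complete_time_s, 53L)
  expect_equal(eps$postpone_time_s, 52L)
})

test_that("a single unanswered instance yields a no-response episode", {
  d <- tiny_dataset()
  d$alert_events$response_time <- as.POSIXct(NA, tz = "UTC")
  d$alert_events$subsequent_action <- "none"
  d$alert_events$override_reason <- NA_character_
  eps <- build_episodes(d)
  expect_equal(eps$final_action, "no_response")
  expect_false(eps$completed)
  expect_true(is.na(eps$complete_time_s))
})

test_that("unmapped override reasons abort naming the token", {
  d <- tiny_dataset()
  d$alert_events$override_reason <- "Snoozed"
  expect_error(build_episodes(d), "Snoozed",
               class = "alertmetrics_validation_error")
})

test_that("toy10 reconstructs nine episodes and conserves instance counts", {
  d <- toy10()
  eps <- build_episodes(d)
  expect_equal(nrow(eps), 9)
  for (kind in c("screening", "support")) {
    expect_equal(sum(eps$n_firings[eps$alert_kind == kind]),
                 sum(d$alert_events$alert_name == kind))
  }
  # one outcome per encounter with a screening firing
  out <- rollup_encounters(eps, d)
  expect_equal(sum(out$screening_fired),
               dplyr::n_distinct(
                 d$alert_events$encounter_id[
                   d$alert_events$alert_name == "screening"]))
})

test_that("modality classification follows the any-interruption rule", {
  expect_equal(determine_modality("chart_open"), "interruptive")
  expect_equal(determine_modality("noninterruptive_display"),
               "noninterruptive")
  expect_equal(determine_modality(c("noninterruptive_display",
                                    "timer_refire")), "interruptive")
  expect_error(determine_modality(character(0)))
})

test_that("documentation requires every configured question answered", {
  rows <- tibble::tibble(
    flowsheet_name = c("Q1", "Q2", "Q3"),
    flowsheet_value = c("Within the past 7 days", "Yes", "Advice given"))
  expect_true(documentation_complete(rows))
  expect_false(documentation_complete(rows[1:2, ]))
  rows$flowsheet_value[3] <- ""
  expect_false(documentation_complete(rows))
  expect_true(documentation_complete(rows[1:2, ],
                                     required_questions = c("Q1", "Q2")))
})

test_that("roll-up separates acknowledged completion from documentation", {
  d <- toy10()
  out <- rollup_encounters(build_episodes(d), d)
  o <- function(id) out[out$encounter_id == id, ]
  # acknowledged and fully documented
  expect_true(o("E01")$screening_ack_completed)
  expect_true(o("E01")$screening_documented)
  # acknowledged with no flowsheet rows: the acknowledged-but-undocumented gap
  expect_true(o("E07")$screening_ack_completed)
  expect_false(o("E07")$screening_documented)
  # acknowledged with partial documentation
  expect_true(o("E06")$screening_ack_completed)
  expect_false(o("E06")$screening_documented)
  # defer-only episode
  expect_true(o("E05")$screening_deferred_any)
  expect_false(o("E05")$screening_ack_completed)
  # not-appropriate episode
  expect_true(o("E03")$screening_not_appropriate)
  # support dispositions
  expect_true(o("E01")$support_no_postpone)
  expect_true(o("E01")$support_ready_to_quit)
  expect_true(o("E01")$support_referral_ordered)
  expect_false(o("E02")$support_no_postpone)
  expect_true(o("E02")$support_deferred_any)
  expect_false(o("E02")$support_discussed)
  # ready-to-quit implies discussed; support flags false without support
  expect_true(all(out$support_discussed[out$support_ready_to_quit]))
  sup_cols <- c("support_no_postpone", "support_discussed",
                "support_ready_to_quit", "support_referral_ordered")
  for (cn in sup_cols) expect_false(any(out[[cn]] & !out$support_fired))
})

test_that("windows are half-open 3-calendar-month intervals from go-live", {
  g <- as.Date("2020-01-06")
  ts <- as.POSIXct(c("2020-01-06 00:00:00", "2020-04-05 23:59:59",
                     "2020-04-06 00:00:00", "2020-10-06 00:00:00",
                     "2021-01-05 23:59:59", "2021-01-06 00:00:00",
                     "2019-12-31 12:00:00"), tz = "UTC")
  expect_equal(window_index(ts, g), c(0L, 0L, 1L, 3L, 3L, NA, NA))
  # toy10 window assignment, including the out-of-window encounter
  d <- toy10()
  out <- rollup_encounters(build_episodes(d), d)
  w <- stats::setNames(out$window_index, out$encounter_id)
  expect_equal(unname(w[c("E01", "E02", "E03", "E04", "E05", "E06", "E07")]),
               c(0L, 1L, 2L, 3L, 0L, 0L, 0L))
})

test_that("relevance mapping must cover every encounter type present", {
  d <- toy10()
  eps <- build_episodes(d)
  expect_error(rollup_encounters(eps, d,
                                 relevance_map = c(office_visit = "relevant")),
               "lab_visit", class = "alertmetrics_config_error")
})

test_that("pipeline outcomes equal the simulator ground truth exactly", {
  sim <- simulate_alerts(random_sim_config(31))
  out <- rollup_encounters(build_episodes(sim$dataset), sim$dataset)
  expect_outcomes_equal_truth(out, sim$ground_truth)
})
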