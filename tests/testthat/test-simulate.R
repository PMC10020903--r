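# event-log simulator: determinism, alert logic, forced regimes

test_that("the same seed reproduces the dataset exactly", {
  a <- simulate_alerts(random_sim_config(5))
  b <- simulate_alerts(random_sim_config(5))
  for (nm in c("patients", "encounters", "clinics", "alert_events",
               "flowsheet")) {
    expect_identical(as.data.frame(a$dataset[[nm]]),
                     as.data.frame(b$dataset[[nm]]))
  }
  expect_identical(as.data.frame(a$ground_truth),
                   as.data.frame(b$ground_truth))
  # a different seed changes the draw
  c_ <- simulate_alerts(random_sim_config(5), seed = 999)
  expect_false(identical(as.data.frame(a$dataset$alert_events),
                         as.data.frame(c_$dataset$alert_events)))
})

test_that("simulated datasets satisfy every integrity and firing rule", {
  for (s in c(11, 12, 13)) {
    sim <- simulate_alerts(random_sim_config(s))
    expect_equal(nrow(validate_dataset(sim$dataset)), 0)
    expect_equal(nrow(conditional_firing_check(sim$dataset)), 0)
    # screening fires only for current/unknown smokers
    ev <- sim$dataset$alert_events
    scr_pat <- unique(ev$patient_id[ev$alert_name == "screening"])
    status <- sim$dataset$patients$smoking_status[
      match(scr_pat, sim$dataset$patients$patient_id)]
    expect_true(all(status %in% c("current", "unknown")))
  }
})

test_that("deterministic regimes force the expected metrics", {
  cl <- tibble::tibble(clinic_id = "C1", name = "C1",
                       go_live_date = as.Date("2020-01-06"),
                       screening_alert = TRUE, support_alert = TRUE,
                       n_encounters = 300L)
  cfg <- sim_config(clinics = cl, p_ack_complete = 1, p_not_appropriate = 0,
                    p_defer_only = 0, p_stop_screening = 1,
                    p_support_postpone = 0, seed = 8)
  sim <- simulate_alerts(cfg)
  eps <- build_episodes(sim$dataset)
  out <- rollup_encounters(eps, sim$dataset)
  expect_equal(completion_rate(out, "ack")$rate, 1)
  expect_equal(firing_rate(eps, "screening")$rate, 1)
  expect_true(all(!out$screening_deferred_any))
  if (any(out$support_fired)) {
    expect_equal(completion_rate(out, "no_postpone")$rate, 1)
  }
})

test_that("postponed interruptive instances refire on the configured timer", {
  cl <- tibble::tibble(clinic_id = "C1", name = "C1",
                       go_live_date = as.Date("2020-01-06"),
                       screening_alert = TRUE, support_alert = FALSE,
                       n_encounters = 200L)
  cfg <- sim_config(clinics = cl, p_stop_screening = 0.4,
                    p_chart_reopen = 0, refire_interval_s = 600, seed = 21)
  sim <- simulate_alerts(cfg)
  ev <- sim$dataset$alert_events |>
    dplyr::arrange(alert_id, firing_time)
  multi <- ev |> dplyr::count(alert_id) |> dplyr::filter(n > 1)
  expect_gt(nrow(multi), 0)
  chains <- ev[ev$alert_id %in% multi$alert_id, ]
  by_alert <- split(chains, chains$alert_id)
  for (ep in by_alert) {
    gaps <- as.numeric(difftime(ep$firing_time[-1],
                                ep$response_time[-nrow(ep)], units = "secs"))
    expect_true(all(gaps == 600))
    expect_true(all(ep$triggering_condition[-1] == "timer_refire"))
  }
})

test_that("conditional firing violations are detected in corrupted data", {
  t0 <- as.POSIXct("2020-02-01 09:00:00", tz = "UTC")
  sup_event <- tibble::tibble(
    alert_id = "B1", alert_instance_id = "B1-01", alert_name = "support",
    encounter_id = "E1", patient_id = "P1",
    firing_time = t0 + 600, response_time = t0 + 650,
    triggering_condition = "chart_open",
    subsequent_action = "acknowledge_override_warning",
    override_reason = "Discussed - Ready to quit",
    signed_order = NA_character_)
  q_rows <- tibble::tibble(
    encounter_id = "E1", flowsheet_name = c("Q1", "Q2"),
    flowsheet_value = c("Within the past 7 days", "Yes"),
    recorded_time = t0 + c(60, 120))

  # support alert without the Q2 answer
  d <- tiny_dataset(events = sup_event, flowsheet = q_rows[1, ])
  v <- conditional_firing_check(d)
  expect_equal(nrow(v), 1)
  expect_match(v$message, "Q2")

  # support alert for a never-smoker
  d2 <- tiny_dataset(events = sup_event, flowsheet = q_rows,
                     smoking_status = "never")
  v2 <- conditional_firing_check(d2)
  expect_equal(nrow(v2), 1)
  expect_equal(v2$rule, "support_requires_positive_screen")

  # screener documented only after the support alert fired
  q_late <- q_rows
  q_late$recorded_time <- t0 + c(700, 800)
  d3 <- tiny_dataset(events = sup_event, flowsheet = q_late)
  expect_equal(nrow(conditional_firing_check(d3)), 2)

  # clean conditional data passes
  d4 <- tiny_dataset(events = sup_event, flowsheet = q_rows)
  expect_equal(nrow(conditional_firing_check(d4)), 0)
})

test_that("invalid configurations are rejected with field names", {
  expect_error(sim_config(p_ack_complete = 1.2), "p_ack_complete",
               class = "alertmetrics_config_error")
  expect_error(sim_config(p_ack_complete = 0.6, p_not_appropriate = 0.3,
                          p_defer_only = 0.2),
               class = "alertmetrics_config_error")
  expect_error(sim_config(refire_interval_s = 0),
               class = "alertmetrics_config_error")
  expect_error(sim_config(smoking_status_dist = c(current = -1, never = 2)),
               class = "alertmetrics_config_error")
})

test_that("behavior probabilities are recovered from moderate simulations", {
  cl <- default_sim_clinics()
  cfg <- sim_config(clinics = cl, seed = 404)
  sim <- simulate_alerts(cfg)
  out <- rollup_encounters(build_episodes(sim$dataset), sim$dataset)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  ack <- completion_rate(out, "ack")
  expect_lt(abs(ack$rate - cfg$p_ack_complete),
            3 * se(cfg$p_ack_complete, ack$denominator))
  np <- completion_rate(out, "no_postpone")
  expect_lt(abs(np$rate - (1 - cfg$p_support_postpone)),
            3 * se(1 - cfg$p_support_postpone, np$denominator))
})
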