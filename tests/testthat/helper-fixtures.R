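# shared fixtures and oracle helpers

toy10_dir <- function() {
  system.file("extdata", "toy10", package = "alertmetrics", mustWork = TRUE)
}

toy10 <- function() read_dataset(toy10_dir(), quiet = TRUE)

# a minimal single-clinic dataset builder for targeted integrity tests
tiny_dataset <- function(events = NULL, flowsheet = NULL,
                         smoking_status = "current") {
  t0 <- as.POSIXct("2020-02-01 09:00:00", tz = "UTC")
  if (is.null(events)) {
    events <- tibble::tibble(
      alert_id = "A1", alert_instance_id = "A1-01",
      alert_name = "screening", encounter_id = "E1", patient_id = "P1",
      firing_time = t0, response_time = t0 + 30,
      triggering_condition = "chart_open",
      subsequent_action = "acknowledge_override_warning",
      override_reason = "Documented in Flowsheet",
      signed_order = NA_character_)
  }
  if (is.null(flowsheet)) {
    flowsheet <- tibble::tibble(encounter_id = character(0),
                                flowsheet_name = character(0),
                                flowsheet_value = character(0),
                                recorded_time = as.POSIXct(character(0),
                                                           tz = "UTC"))
  }
  alert_dataset(
    patients = tibble::tibble(patient_id = "P1", sex = "female",
                              race = "white",
                              smoking_status = smoking_status),
    encounters = tibble::tibble(encounter_id = "E1", patient_id = "P1",
                                clinic_id = "C1",
                                encounter_type = "office_visit",
                                start_time = t0),
    clinics = tibble::tibble(clinic_id = "C1", name = "Clinic 1",
                             go_live_date = as.Date("2020-01-06"),
                             screening_alert = TRUE, support_alert = TRUE),
    alert_events = events,
    flowsheet = flowsheet
  )
}

# metrics recomputed directly from a simulator ground-truth ledger; the
# independent oracle for pipeline metric values
truth_rate <- function(gt, flag, denom) {
  gt <- gt[!is.na(gt$window_index), ]
  sum(gt[[flag]] & gt[[denom]]) / sum(gt[[denom]])
}

# compare the pipeline's encounter outcomes with a ground-truth ledger,
# column by column, exactly
expect_outcomes_equal_truth <- function(out, gt) {
  expect_setequal(out$encounter_id, gt$encounter_id)
  out <- out[match(gt$encounter_id, out$encounter_id), ]
  for (cn in intersect(names(gt), names(out))) {
    expect_equal(out[[cn]], gt[[cn]], info = paste("column", cn),
                 ignore_attr = TRUE)
  }
}

# Monte-Carlo permutation p for a 2x2 table: permuting group labels fixes
# both margins, so the permuted successes in group 1 are hypergeometric
permutation_p <- function(x1, n1, x2, n2, draws = 1e5, seed = 1234) {
  set.seed(seed)
  total <- x1 + x2
  obs <- abs(x1 / n1 - x2 / n2)
  sim <- stats::rhyper(draws, total, n1 + n2 - total, n1)
  mean(abs(sim / n1 - (total - sim) / n2) >= obs - 1e-12)
}
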