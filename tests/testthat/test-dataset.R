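# event-log model: reading, writing, validation

test_that("toy10 fixture reads with the authored table counts", {
  d <- toy10()
  expect_s3_class(d, "alert_dataset")
  expect_equal(nrow(d$patients), 10)
  expect_equal(nrow(d$encounters), 10)
  expect_equal(nrow(d$clinics), 2)
  expect_equal(nrow(d$alert_events), 14)
  expect_equal(nrow(d$flowsheet), 6)
  expect_s3_class(d$encounters$start_time, "POSIXct")
  expect_equal(attr(d$alert_events$firing_time, "tzone"), "UTC")
})

test_that("an events table with headers only yields a valid empty dataset", {
  dir <- withr::local_tempdir()
  file.copy(list.files(toy10_dir(), full.names = TRUE), dir)
  writeLines(paste(c("alert_id", "alert_instance_id", "alert_name",
                     "encounter_id", "patient_id", "firing_time",
                     "response_time", "triggering_condition",
                     "subsequent_action", "override_reason", "signed_order"),
                   collapse = ","),
             file.path(dir, "alert_events.csv"))
  d <- read_dataset(dir, quiet = TRUE)
  expect_equal(nrow(d$alert_events), 0)
  expect_equal(nrow(validate_dataset(d)), 0)
})

test_that("schema errors name the offending table, column or row", {
  dir <- withr::local_tempdir()
  file.copy(list.files(toy10_dir(), full.names = TRUE), dir)
  file.remove(file.path(dir, "flowsheet.csv"))
  expect_error(read_dataset(dir, quiet = TRUE), "flowsheet",
               class = "alertmetrics_schema_error")

  dir2 <- withr::local_tempdir()
  file.copy(list.files(toy10_dir(), full.names = TRUE), dir2)
  pats <- readLines(file.path(dir2, "patients.csv"))
  writeLines(gsub("smoking_status", "smoker", pats),
             file.path(dir2, "patients.csv"))
  expect_error(read_dataset(dir2, quiet = TRUE), "smoking_status",
               class = "alertmetrics_schema_error")

  dir3 <- withr::local_tempdir()
  file.copy(list.files(toy10_dir(), full.names = TRUE), dir3)
  enc <- readLines(file.path(dir3, "encounters.csv"))
  enc[3] <- sub("2020-04-15T10:00:00Z", "not-a-time", enc[3])
  writeLines(enc, file.path(dir3, "encounters.csv"))
  expect_error(read_dataset(dir3, quiet = TRUE), "row 2",
               class = "alertmetrics_schema_error")
})

test_that("validation reports dangling references, temporal and grouping violations", {
  t0 <- as.POSIXct("2020-02-01 09:00:00", tz = "UTC")
  base <- tiny_dataset()

  # dangling encounter reference
  d <- base
  d$alert_events$encounter_id <- "E-MISSING"
  v <- validate_dataset(d)
  expect_true("event_encounter_ref" %in% v$rule)

  # response before firing
  d <- base
  d$alert_events$response_time <- t0 - 5
  v <- validate_dataset(d)
  expect_equal(v$rule, "response_after_firing")

  # two instances of one alert_id on different encounters
  d <- tiny_dataset(events = tibble::tibble(
    alert_id = c("A1", "A1"), alert_instance_id = c("A1-01", "A1-02"),
    alert_name = "screening", encounter_id = c("E1", "E2"),
    patient_id = "P1", firing_time = c(t0, t0 + 700),
    response_time = c(t0 + 10, t0 + 710),
    triggering_condition = c("chart_open", "timer_refire"),
    subsequent_action = "acknowledge_override_warning",
    override_reason = c("Defer", "Documented in Flowsheet"),
    signed_order = NA_character_))
  d$encounters <- dplyr::bind_rows(
    d$encounters, dplyr::mutate(d$encounters, encounter_id = "E2"))
  v <- validate_dataset(d)
  expect_true("alert_shared_encounter" %in% v$rule)
  expect_equal(sum(v$rule == "alert_shared_encounter"), 1)

  # signed order on a screening alert
  d <- base
  d$alert_events$signed_order <- "REF-TOBACCO"
  expect_true("signed_order_support_only" %in% validate_dataset(d)$rule)

  # unmapped override reason
  d <- base
  d$alert_events$override_reason <- "Snoozed"
  expect_true("vocabulary_coverage" %in% validate_dataset(d)$rule)

  # event before go-live
  d <- base
  d$clinics$go_live_date <- as.Date("2020-03-01")
  expect_true("event_after_go_live" %in% validate_dataset(d)$rule)
})

test_that("validate_dataset is pure and clean fixtures yield no violations", {
  d <- toy10()
  v1 <- validate_dataset(d)
  v2 <- validate_dataset(d)
  expect_equal(nrow(v1), 0)
  expect_identical(v1, v2)
})

test_that("write-then-read is the identity on valid datasets", {
  # property over randomly generated valid datasets, plus the toy fixture
  cases <- c(list(toy10()), lapply(c(101, 202), function(s) {
    simulate_alerts(random_sim_config(s))$dataset
  }))
  for (d in cases) {
    dir <- withr::local_tempdir()
    write_dataset(d, dir)
    d2 <- read_dataset(dir, quiet = TRUE)
    for (nm in c("patients", "encounters", "clinics", "alert_events",
                 "flowsheet")) {
      a <- dplyr::arrange(d[[nm]], dplyr::across(dplyr::everything()))
      b <- dplyr::arrange(d2[[nm]], dplyr::across(dplyr::everything()))
      expect_equal(as.data.frame(a), as.data.frame(b),
                   info = paste("table", nm))
    }
    expect_identical(d2$vocabulary, d$vocabulary)
  }
})

test_that("JSONL round-trips match the CSV representation", {
  d <- toy10()
  dir <- withr::local_tempdir()
  write_dataset(d, dir, format = "jsonl")
  expect_true(file.exists(file.path(dir, "alert_events.jsonl")))
  d2 <- read_dataset(dir, quiet = TRUE)
  expect_equal(as.data.frame(dplyr::arrange(d2$alert_events,
                                            alert_instance_id)),
               as.data.frame(dplyr::arrange(d$alert_events,
                                            alert_instance_id)))
  expect_equal(nrow(validate_dataset(d2)), 0)
})

test_that("optional fields written as empty strings read back as missing", {
  d <- toy10()
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  raw <- readr::read_csv(file.path(dir, "alert_events.csv"),
                         col_types = readr::cols(.default = "c"),
                         na = character())
  expect_true(any(raw$response_time == ""))
  d2 <- read_dataset(dir, quiet = TRUE)
  expect_true(any(is.na(d2$alert_events$response_time)))
})
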