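# Event-log data model: construction, I/O and validation.

TIME_FORMAT <- "%Y-%m-%dT%H:%M:%SZ"

DATASET_SCHEMAS <- list(
  patients = c("patient_id", "sex", "race", "smoking_status"),
  encounters = c("encounter_id", "patient_id", "clinic_id", "encounter_type",
                 "start_time"),
  clinics = c("clinic_id", "name", "go_live_date", "screening_alert",
              "support_alert"),
  alert_events = c("alert_id", "alert_instance_id", "alert_name",
                   "encounter_id", "patient_id", "firing_time",
                   "response_time", "triggering_condition",
                   "subsequent_action", "override_reason", "signed_order"),
  flowsheet = c("encounter_id", "flowsheet_name", "flowsheet_value",
                "recorded_time")
)

#' Assemble an alert event-log dataset
#'
#' Bundles the five tables of the event-log model plus the action vocabulary
#' into one object. Timestamps are POSIXct in UTC at whole-second resolution;
#' optional fields (e.g. `response_time`, `signed_order`) are `NA` when
#' absent. Construction checks column presence and types only; referential
#' and temporal integrity is checked by [validate_dataset()].
#'
#' @param patients Tibble: `patient_id`, `sex`, `race`, `smoking_status`.
#' @param encounters Tibble: `encounter_id`, `patient_id`, `clinic_id`,
#'   `encounter_type`, `start_time`.
#' @param clinics Tibble: `clinic_id`, `name`, `go_live_date` (Date), and
#'   logical columns `screening_alert`, `support_alert` saying which alerts
#'   the clinic implemented.
#' @param alert_events Tibble of alert instances; one row per firing.
#' @param flowsheet Tibble of screener-question documentation rows.
#' @param vocabulary Named character vector mapping raw `override_reason`
#'   tokens to canonical actions; defaults to [default_vocabulary()].
#' @return An object of class `alert_dataset`.
#' @export
alert_dataset <- function(patients, encounters, clinics, alert_events,
                          flowsheet, vocabulary = default_vocabulary()) {
  tables <- list(patients = patients, encounters = encounters,
                 clinics = clinics, alert_events = alert_events,
                 flowsheet = flowsheet)
  for (nm in names(DATASET_SCHEMAS)) {
    missing <- setdiff(DATASET_SCHEMAS[[nm]], names(tables[[nm]]))
    if (length(missing) > 0) {
      abort_schema(paste0("table '", nm, "' is missing column(s): ",
                          paste(missing, collapse = ", ")))
    }
    tables[[nm]] <- tibble::as_tibble(tables[[nm]])[, DATASET_SCHEMAS[[nm]]]
  }
  tables$clinics$go_live_date <- as.Date(tables$clinics$go_live_date)
  tables$clinics$screening_alert <- as.logical(tables$clinics$screening_alert)
  tables$clinics$support_alert <- as.logical(tables$clinics$support_alert)
  for (spec in list(c("encounters", "start_time"),
                    c("alert_events", "firing_time"),
                    c("alert_events", "response_time"),
                    c("flowsheet", "recorded_time"))) {
    tables[[spec[1]]][[spec[2]]] <- as_utc_time(tables[[spec[1]]][[spec[2]]],
                                                paste0(spec[1], ".", spec[2]))
  }
  structure(c(tables, list(vocabulary = vocabulary)), class = "alert_dataset")
}

# parse/coerce timestamps to POSIXct UTC, truncated to whole seconds;
# character input must be ISO-8601
as_utc_time <- function(x, what) {
  if (inherits(x, "POSIXct")) {
    out <- lubridate::with_tz(x, "UTC")
  } else if (is.character(x) || all(is.na(x))) {
    x <- as.character(x)
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
    for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
      idx <- is.na(out) & !is.na(x)
      if (!any(idx)) break
      out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
    }
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort_schema(paste0("unparseable timestamp in ", what, " at row ",
                          bad[1], ": '", x[bad[1]], "'"))
    }
  } else {
    abort_schema(paste0("column ", what, " is not a timestamp"))
  }
  # whole-second resolution, UTC
  as.POSIXct(floor(as.numeric(out)), origin = "1970-01-01", tz = "UTC")
}

format_utc <- function(x) {
  out <- format(x, format = TIME_FORMAT, tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

#' @export
print.alert_dataset <- function(x, ...) {
  cat("<alert_dataset>\n")
  for (nm in names(DATASET_SCHEMAS)) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  cat(sprintf("  vocabulary   %6d mapped override reasons\n",
              length(x$vocabulary)))
  invisible(x)
}

#' Read an event-log dataset from disk
#'
#' Reads the five tables (`patients`, `encounters`, `clinics`,
#' `alert_events`, `flowsheet`) from a directory, as CSV (`<table>.csv`) or
#' JSON lines (`<table>.jsonl`, one record per line), plus the action
#' vocabulary. CSV dialect: comma-separated, UTF-8, mandatory header row,
#' empty string encodes a missing optional value. Timestamps must be
#' ISO-8601; they are stored in UTC at whole-second resolution.
#'
#' @param root_path Directory containing the tables.
#' @param vocab_path Path to a vocabulary YAML; defaults to
#'   `vocabulary.yaml` inside `root_path` when present, else
#'   [default_vocabulary()].
#' @param quiet Suppress the per-table row-count message.
#' @return An [alert_dataset()].
#' @export
read_dataset <- function(root_path, vocab_path = NULL, quiet = FALSE) {
  if (!dir.exists(root_path)) {
    abort_schema(paste0("dataset directory not found: ", root_path))
  }
  tables <- lapply(names(DATASET_SCHEMAS), function(nm) {
    read_table_file(root_path, nm)
  })
  names(tables) <- names(DATASET_SCHEMAS)
  if (is.null(vocab_path)) {
    default_path <- file.path(root_path, "vocabulary.yaml")
    vocab <- if (file.exists(default_path)) read_vocabulary(default_path)
             else default_vocabulary()
  } else {
    vocab <- read_vocabulary(vocab_path)
  }
  d <- alert_dataset(tables$patients, tables$encounters, tables$clinics,
                     tables$alert_events, tables$flowsheet, vocab)
  if (!quiet) {
    counts <- vapply(names(DATASET_SCHEMAS), function(nm) nrow(d[[nm]]), 0L)
    message("read dataset from ", root_path, ": ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  d
}

read_table_file <- function(root_path, nm) {
  csv <- file.path(root_path, paste0(nm, ".csv"))
  jsonl <- file.path(root_path, paste0(nm, ".jsonl"))
  if (file.exists(csv)) {
    df <- readr::read_csv(csv, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE)
    # empty string = null for optional fields
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::everything(), ~ dplyr::if_else(.x == "", NA_character_, .x)))
  } else if (file.exists(jsonl)) {
    lines <- readLines(jsonl, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      df <- tibble::as_tibble(stats::setNames(
        replicate(length(DATASET_SCHEMAS[[nm]]), character(0),
                  simplify = FALSE), DATASET_SCHEMAS[[nm]]))
    } else {
      recs <- lapply(lines, jsonlite::fromJSON)
      df <- dplyr::bind_rows(lapply(recs, function(r) {
        r[vapply(r, is.null, TRUE)] <- NA
        tibble::as_tibble(lapply(r, as.character))
      }))
    }
  } else {
    abort_schema(paste0("missing table '", nm, "' in ", root_path,
                        " (expected ", nm, ".csv or ", nm, ".jsonl)"))
  }
  missing <- setdiff(DATASET_SCHEMAS[[nm]], names(df))
  if (length(missing) > 0) {
    abort_schema(paste0("table '", nm, "' is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df
}

#' Write an event-log dataset to disk
#'
#' Inverse of [read_dataset()]: writes the five tables plus
#' `vocabulary.yaml` so that reading the directory back reproduces the
#' dataset field-for-field. Optional fields that are `NA` are written as the
#' empty string (CSV) or omitted keys (JSONL). Rows are written in a
#' canonical sort order so identical datasets produce byte-identical files.
#'
#' @param d An [alert_dataset()].
#' @param root_path Output directory (created if needed).
#' @param format `"csv"` (default) or `"jsonl"`.
#' @return `root_path`, invisibly.
#' @export
write_dataset <- function(d, root_path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(d, "alert_dataset"))
  dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root_path)) {
    rlang::abort(paste0("cannot create output directory: ", root_path),
                 class = "alertmetrics_io_error")
  }
  sort_keys <- list(patients = "patient_id", encounters = "encounter_id",
                    clinics = "clinic_id",
                    alert_events = c("alert_id", "firing_time",
                                     "alert_instance_id"),
                    flowsheet = c("encounter_id", "flowsheet_name",
                                  "recorded_time"))
  for (nm in names(DATASET_SCHEMAS)) {
    df <- d[[nm]]
    df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(sort_keys[[nm]])))
    out <- dplyr::mutate(df, dplyr::across(
      dplyr::where(~ inherits(.x, "POSIXct")), format_utc))
    if ("go_live_date" %in% names(out)) {
      out$go_live_date <- format(out$go_live_date, "%Y-%m-%d")
    }
    out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.character))
    path <- file.path(root_path, paste0(nm, ".", format))
    if (format == "csv") {
      readr::write_csv(out, path, na = "")
    } else {
      json <- character(0)
      if (nrow(out) > 0) {
        json <- vapply(seq_len(nrow(out)), function(i) {
          rec <- as.list(out[i, ])
          rec <- rec[!vapply(rec, is.na, TRUE)]
          as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
        }, character(1))
      }
      con <- file(path, open = "wb")
      writeLines(json, con)
      close(con)
    }
  }
  yaml::write_yaml(as.list(d$vocabulary),
                   file.path(root_path, "vocabulary.yaml"))
  invisible(root_path)
}

# typed empty tables matching the dataset schemas
empty_dataset_tables <- function() {
  pos0 <- as.POSIXct(character(0), tz = "UTC")
  chr0 <- character(0)
  list(
    patients = tibble::tibble(patient_id = chr0, sex = chr0, race = chr0,
                              smoking_status = chr0),
    encounters = tibble::tibble(encounter_id = chr0, patient_id = chr0,
                                clinic_id = chr0, encounter_type = chr0,
                                start_time = pos0),
    clinics = tibble::tibble(clinic_id = chr0, name = chr0,
                             go_live_date = as.Date(chr0),
                             screening_alert = logical(0),
                             support_alert = logical(0)),
    alert_events = tibble::tibble(alert_id = chr0, alert_instance_id = chr0,
                                  alert_name = chr0, encounter_id = chr0,
                                  patient_id = chr0, firing_time = pos0,
                                  response_time = pos0,
                                  triggering_condition = chr0,
                                  subsequent_action = chr0,
                                  override_reason = chr0, signed_order = chr0),
    flowsheet = tibble::tibble(encounter_id = chr0, flowsheet_name = chr0,
                               flowsheet_value = chr0, recorded_time = pos0)
  )
}

# validation -------------------------------------------------------------------

violation <- function(rule, table, locator, message) {
  tibble::tibble(rule = rule, table = table, locator = as.character(locator),
                 message = message)
}

#' Validate referential, temporal and vocabulary integrity
#'
#' Checks every invariant of the event-log model and returns the violations
#' as a tibble rather than throwing: duplicate primary keys, enum domains,
#' dangling references, response before firing, alert instances of one alert
#' id spanning several encounters or patients, signed orders on
#' non-support alerts, alert events firing before their clinic's go-live
#' date, flowsheet rows for unknown screener questions, and raw override
#' reasons not covered by the action vocabulary. The input is never mutated;
#' the function is pure.
#'
#' @param d An [alert_dataset()].
#' @param required_questions Names of the configured screener questions.
#' @return Tibble with columns `rule`, `table`, `locator`, `message`;
#'   zero rows when the dataset is valid.
#' @export
validate_dataset <- function(d, required_questions = c("Q1", "Q2", "Q3")) {
  stopifnot(inherits(d, "alert_dataset"))
  v <- list()
  add <- function(x) v[[length(v) + 1]] <<- x

  dup_check <- function(ids, rule, table) {
    dups <- unique(ids[duplicated(ids)])
    if (length(dups) > 0) {
      add(violation(rule, table, dups,
                    paste0("duplicate primary key: ", dups)))
    }
  }
  dup_check(d$patients$patient_id, "unique_patient_id", "patients")
  dup_check(d$encounters$encounter_id, "unique_encounter_id", "encounters")
  dup_check(d$clinics$clinic_id, "unique_clinic_id", "clinics")
  dup_check(d$alert_events$alert_instance_id, "unique_alert_instance_id",
            "alert_events")

  enum_check <- function(values, levels, rule, table, ids) {
    bad <- which(!is.na(values) & !(values %in% levels))
    if (length(bad) > 0) {
      add(violation(rule, table, ids[bad],
                    paste0("value '", values[bad], "' outside {",
                           paste(levels, collapse = ", "), "}")))
    }
  }
  enum_check(d$patients$sex, SEX_LEVELS, "sex_enum", "patients",
             d$patients$patient_id)
  enum_check(d$patients$race, RACE_LEVELS, "race_enum", "patients",
             d$patients$patient_id)
  enum_check(d$patients$smoking_status, SMOKING_LEVELS, "smoking_enum",
             "patients", d$patients$patient_id)
  ev <- d$alert_events
  enum_check(ev$alert_name, ALERT_KINDS, "alert_name_enum", "alert_events",
             ev$alert_instance_id)
  enum_check(ev$triggering_condition, TRIGGER_LEVELS, "trigger_enum",
             "alert_events", ev$alert_instance_id)
  enum_check(ev$subsequent_action, SUBSEQUENT_ACTIONS,
             "subsequent_action_enum", "alert_events", ev$alert_instance_id)

  ref_check <- function(ids, universe, rule, table, locators) {
    bad <- which(!is.na(ids) & !(ids %in% universe))
    if (length(bad) > 0) {
      add(violation(rule, table, locators[bad],
                    paste0("unresolved reference: ", ids[bad])))
    }
  }
  ref_check(d$encounters$patient_id, d$patients$patient_id,
            "encounter_patient_ref", "encounters", d$encounters$encounter_id)
  ref_check(d$encounters$clinic_id, d$clinics$clinic_id,
            "encounter_clinic_ref", "encounters", d$encounters$encounter_id)
  ref_check(ev$encounter_id, d$encounters$encounter_id, "event_encounter_ref",
            "alert_events", ev$alert_instance_id)
  ref_check(ev$patient_id, d$patients$patient_id, "event_patient_ref",
            "alert_events", ev$alert_instance_id)
  ref_check(d$flowsheet$encounter_id, d$encounters$encounter_id,
            "flowsheet_encounter_ref", "flowsheet",
            d$flowsheet$encounter_id)

  bad <- which(!is.na(ev$response_time) & ev$response_time < ev$firing_time)
  if (length(bad) > 0) {
    add(violation("response_after_firing", "alert_events",
                  ev$alert_instance_id[bad],
                  "response_time precedes firing_time"))
  }

  if (nrow(ev) > 0) {
    shared <- ev |>
      dplyr::summarise(n_enc = dplyr::n_distinct(.data$encounter_id),
                       n_pat = dplyr::n_distinct(.data$patient_id),
                       .by = "alert_id")
    bad <- shared$alert_id[shared$n_enc > 1 | shared$n_pat > 1]
    if (length(bad) > 0) {
      add(violation("alert_shared_encounter", "alert_events", bad,
                    paste0("instances of alert_id ", bad,
                           " span multiple encounters or patients")))
    }
  }

  bad <- which(!is.na(ev$signed_order) & ev$alert_name != "support")
  if (length(bad) > 0) {
    add(violation("signed_order_support_only", "alert_events",
                  ev$alert_instance_id[bad],
                  "signed_order on a non-support alert event"))
  }

  if (nrow(ev) > 0) {
    ec <- d$encounters[, c("encounter_id", "clinic_id")]
    joined <- dplyr::left_join(ev, ec, by = "encounter_id") |>
      dplyr::left_join(d$clinics[, c("clinic_id", "go_live_date")],
                       by = "clinic_id")
    bad <- which(!is.na(joined$go_live_date) &
                   joined$firing_time <
                     as.POSIXct(joined$go_live_date, tz = "UTC"))
    if (length(bad) > 0) {
      add(violation("event_after_go_live", "alert_events",
                    ev$alert_instance_id[bad],
                    "alert fired before the clinic's go-live date"))
    }
  }

  bad <- which(!(d$flowsheet$flowsheet_name %in% required_questions))
  if (length(bad) > 0) {
    add(violation("flowsheet_question_set", "flowsheet",
                  d$flowsheet$encounter_id[bad],
                  paste0("flowsheet_name '", d$flowsheet$flowsheet_name[bad],
                         "' not in the configured question set")))
  }

  acked <- ev$subsequent_action == "acknowledge_override_warning"
  tokens <- trimws(ev$override_reason[acked])
  unmapped <- which(!is.na(tokens) & !(tokens %in% names(d$vocabulary)))
  if (length(unmapped) > 0) {
    add(violation("vocabulary_coverage", "alert_events",
                  ev$alert_instance_id[acked][unmapped],
                  paste0("override_reason '", tokens[unmapped],
                         "' not covered by the action vocabulary")))
  }

  if (length(v) == 0) {
    violation(character(0), character(0), character(0), character(0))
  } else {
    dplyr::bind_rows(v)
  }
}
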