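# Deterministic calibration expander: realizes per-clinic aggregate counts
# as an event-level dataset whose pipeline reconstruction reproduces every
# input count exactly. No randomness is involved, so re-expanding the same
# counts yields a byte-identical dataset.

#' Read calibration counts from YAML
#'
#' The file lists, per clinic and alert kind, the encounter counts of each
#' disposition category, the relevance split, the number of interruptive
#' firings beyond one per episode, and fixed handling durations per action
#' class. See the packaged `calibration-example.yaml` for the full schema.
#'
#' @param path Path to a calibration YAML file.
#' @return A validated `calibration_counts` object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("calibration file not found: ", path))
  }
  calibration_counts(yaml::read_yaml(path))
}

#' Construct calibration counts from a list
#'
#' @param x List with elements `durations_s`, `encounter_types` and
#'   `clinics` (each clinic: `clinic_id`, `name`, `go_live_date`, a
#'   `screening` count block and optionally a `support` count block).
#' @return A validated `calibration_counts` object.
#' @export
calibration_counts <- function(x) {
  x <- normalize_calibration(x)
  obj <- structure(x, class = "calibration_counts")
  validate_calibration(obj)
  obj
}

# fill optional fields: count fields default to 0, durations and encounter
# types to the standard constants
normalize_calibration <- function(x) {
  x$durations_s <- utils::modifyList(
    list(screening_complete = 53, screening_postpone = 52,
         support_complete = 50, support_postpone = 67, other = 10),
    as.list(x$durations_s %||% list()))
  x$encounter_types <- utils::modifyList(
    list(relevant = c("office_visit", "initial_consult", "follow_up"),
         less_relevant = c("lab_visit", "treatment_visit")),
    as.list(x$encounter_types %||% list()))
  x$clinics <- lapply(x$clinics, function(cl) {
    cl$name <- cl$name %||% cl$clinic_id
    cl$go_live_date <- cl$go_live_date %||% "2020-01-06"
    zeros <- function(block, fields) {
      utils::modifyList(stats::setNames(as.list(rep(0L, length(fields))),
                                        fields),
                        as.list(block %||% list()))
    }
    cl$screening <- zeros(cl$screening, SCREENING_COUNT_FIELDS)
    if (!is.null(cl$support)) {
      cl$support <- zeros(cl$support, SUPPORT_COUNT_FIELDS)
    }
    cl
  })
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Example calibration bundled with the package
#'
#' Per-clinic counts for a seven-clinic, 12-month monitoring period of a
#' two-alert tobacco-cessation program. Aggregates reproduce the program's
#' published monitoring summary; the per-clinic allocations are synthetic
#' realizations consistent with the published per-clinic rates (see the
#' comments in `calibration-example.yaml`).
#'
#' @return A `calibration_counts` object.
#' @export
example_calibration <- function() {
  read_calibration(system.file("extdata", "calibration-example.yaml",
                               package = "alertmetrics", mustWork = TRUE))
}

SCREENING_COUNT_FIELDS <- c("fired", "ack_completed", "ack_interruptive",
                            "documented", "not_appropriate", "defer_only",
                            "no_response", "less_relevant_fired",
                            "less_relevant_ack",
                            "extra_interruptive_firings")
SUPPORT_COUNT_FIELDS <- c("fired", "discussed", "discussed_postponed",
                          "ready_to_quit", "referral", "extra_firings")

validate_calibration <- function(counts) {
  fail <- function(clinic, msg) {
    abort_config(paste0("calibration inconsistency [", clinic, "]: ", msg))
  }
  need <- function(cond, clinic, msg) if (!cond) fail(clinic, msg)
  if (is.null(counts$clinics) || length(counts$clinics) == 0) {
    abort_config("calibration lists no clinics")
  }
  dur <- counts$durations_s
  need(all(c("screening_complete", "screening_postpone", "support_complete",
             "support_postpone", "other") %in% names(dur)),
       "durations_s", "missing duration class")
  et <- counts$encounter_types
  need(length(et$relevant) > 0 && length(et$less_relevant) > 0,
       "encounter_types", "need both relevant and less_relevant type lists")
  for (cl in counts$clinics) {
    id <- cl$clinic_id
    s <- cl$screening
    need(all(SCREENING_COUNT_FIELDS %in% names(s)), id,
         paste0("screening block missing field(s): ",
                paste(setdiff(SCREENING_COUNT_FIELDS, names(s)),
                      collapse = ", ")))
    need(s$ack_completed + s$not_appropriate + s$defer_only +
           s$no_response == s$fired, id,
         "ack_completed + not_appropriate + defer_only + no_response != fired")
    need(s$ack_interruptive <= s$ack_completed, id,
         "ack_interruptive > ack_completed")
    need(s$documented <= s$fired, id, "documented > fired")
    need(s$less_relevant_ack <= min(s$ack_completed, s$less_relevant_fired),
         id, "less_relevant_ack > min(ack_completed, less_relevant_fired)")
    need(s$less_relevant_fired - s$less_relevant_ack <=
           s$fired - s$ack_completed, id,
         "less_relevant non-ack encounters exceed non-ack encounters")
    need(s$extra_interruptive_firings >= 0, id,
         "extra_interruptive_firings negative")
    need(s$ack_interruptive > 0 || s$extra_interruptive_firings == 0, id,
         "extra firings without any interruptive completing encounter")
    if (!is.null(cl$support)) {
      p <- cl$support
      need(all(SUPPORT_COUNT_FIELDS %in% names(p)), id,
           paste0("support block missing field(s): ",
                  paste(setdiff(SUPPORT_COUNT_FIELDS, names(p)),
                        collapse = ", ")))
      need(p$fired <= s$fired, id, "support fired > screening fired")
      need(p$discussed <= p$fired, id, "discussed > support fired")
      need(p$discussed_postponed <= p$discussed, id,
           "discussed_postponed > discussed")
      need(p$ready_to_quit <= p$discussed, id, "ready_to_quit > discussed")
      need(p$referral <= p$ready_to_quit, id, "referral > ready_to_quit")
      if (p$discussed_postponed == 0) {
        need(p$extra_firings == 0, id,
             "extra support firings without postponed encounters")
      } else {
        need(p$extra_firings >= p$discussed_postponed, id,
             "extra support firings fewer than postponed encounters")
      }
    }
  }
  invisible(counts)
}

# round-robin distribution of `extra` items over `n` slots: first
# (extra mod n) slots get one more
distribute_extras <- function(extra, n) {
  if (n == 0) return(integer(0))
  base <- extra %/% n
  rem <- extra %% n
  base + as.integer(seq_len(n) <= rem)
}

#' Expand calibration counts into an event-level dataset
#'
#' Deterministically emits the minimal event log whose pipeline
#' reconstruction reproduces every input count exactly: one encounter (and
#' patient) per fired screening alert, disposition categories assigned by
#' index blocks, handling durations set to the fixed per-class constants,
#' and interruptive firings beyond one per episode realized as
#' defer-then-timer-refire chains distributed round-robin (screening: over
#' completing interruptive encounters; support: over the postponed-discussed
#' block, since support postponement counts are themselves calibrated).
#' Encounter dates cycle deterministically over the 12 months after each
#' clinic's go-live, so all four 3-month windows are populated.
#'
#' @param counts A `calibration_counts` object (see [read_calibration()]).
#' @return An [alert_dataset()].
#' @export
expand_calibration <- function(counts) {
  if (!inherits(counts, "calibration_counts")) {
    counts <- calibration_counts(counts)
  }
  validate_calibration(counts)
  dur <- counts$durations_s
  et <- counts$encounter_types
  parts <- lapply(counts$clinics, expand_clinic, dur = dur, et = et)

  clinics <- tibble::tibble(
    clinic_id = vapply(counts$clinics, `[[`, "", "clinic_id"),
    name = vapply(counts$clinics, `[[`, "", "name"),
    go_live_date = as.Date(vapply(counts$clinics, `[[`, "", "go_live_date")),
    screening_alert = TRUE,
    support_alert = vapply(counts$clinics,
                           function(cl) !is.null(cl$support), TRUE)
  )
  empties <- empty_dataset_tables()
  bind_or_empty <- function(what) {
    out <- dplyr::bind_rows(lapply(parts, `[[`, what))
    if (nrow(out) == 0) empties[[sub("events", "alert_events", what)]]
    else out
  }
  alert_dataset(
    patients = bind_or_empty("patients"),
    encounters = bind_or_empty("encounters"),
    clinics = clinics,
    alert_events = bind_or_empty("events"),
    flowsheet = bind_or_empty("flowsheet")
  )
}

expand_clinic <- function(cl, dur, et) {
  s <- cl$screening
  n <- s$fired
  go_live <- as.Date(cl$go_live_date)
  if (n == 0) {
    return(list(patients = NULL, encounters = NULL, events = NULL,
                flowsheet = NULL))
  }
  j <- seq_len(n)
  category <- dplyr::case_when(
    j <= s$ack_completed ~ "ack",
    j <= s$ack_completed + s$not_appropriate ~ "not_appropriate",
    j <= s$ack_completed + s$not_appropriate + s$defer_only ~ "defer_only",
    TRUE ~ "no_response"
  )
  interruptive <- (category == "ack" & j <= s$ack_interruptive) |
    category == "defer_only"
  documented <- j <= s$documented
  extra <- integer(n)
  extra[seq_len(s$ack_interruptive)] <-
    distribute_extras(s$extra_interruptive_firings, s$ack_interruptive)

  less_nonack <- s$less_relevant_fired - s$less_relevant_ack
  less <- (j > s$ack_completed - s$less_relevant_ack &
             j <= s$ack_completed) | (j > n - less_nonack)

  sup <- cl$support
  m <- if (is.null(sup)) 0L else sup$fired
  is_support <- j <= m

  encounter_id <- sprintf("%s-E%05d", cl$clinic_id, j)
  patient_id <- sprintf("%s-P%05d", cl$clinic_id, j)
  patients <- tibble::tibble(
    patient_id = patient_id,
    sex = ifelse(j %% 2 == 1, "female", "male"),
    race = c("white", "african_american", "white", "other",
             "white")[(j - 1) %% 5 + 1],
    smoking_status = ifelse(is_support | j %% 2 == 1, "current", "unknown")
  )
  rel_types <- et$relevant
  less_types <- et$less_relevant
  encounter_type <- ifelse(
    less, less_types[(j - 1) %% length(less_types) + 1],
    rel_types[(j - 1) %% length(rel_types) + 1])
  start_time <- as.POSIXct(go_live, tz = "UTC") +
    ((j * 97) %% 360) * 86400 + 9 * 3600 + (j %% 50) * 60
  encounters <- tibble::tibble(
    encounter_id = encounter_id, patient_id = patient_id,
    clinic_id = cl$clinic_id, encounter_type = encounter_type,
    start_time = start_time
  )

  # screening events ----------------------------------------------------------
  n_inst <- ifelse(category == "ack" & interruptive, 1L + extra, 1L)
  idx <- rep(j, n_inst)
  k <- sequence(n_inst)
  cat_i <- category[idx]
  is_defer <- (cat_i == "ack" & k < n_inst[idx]) | cat_i == "defer_only"
  action <- dplyr::case_when(
    is_defer ~ "defer",
    cat_i == "ack" ~ "ack_complete_screening",
    cat_i == "not_appropriate" ~ "not_appropriate",
    TRUE ~ "no_response"
  )
  dur_s <- dplyr::case_when(
    action == "defer" & k == 1 & cat_i == "ack" ~ as.integer(dur$screening_postpone),
    action == "defer" & cat_i == "defer_only" ~ as.integer(dur$screening_postpone),
    action == "defer" ~ 0L,
    action == "ack_complete_screening" ~ as.integer(dur$screening_complete),
    action == "not_appropriate" ~ as.integer(dur$other),
    TRUE ~ NA_integer_
  )
  scr_events <- build_fixed_events(
    idx = idx, k = k, n_inst = n_inst, dur_s = dur_s, action = action,
    interruptive = interruptive, first_time = start_time,
    encounter_id = encounter_id, patient_id = patient_id,
    kind = "screening", signed = NULL
  )
  # end of the screening episode per encounter (last firing + duration)
  t_resp <- scr_events$firing_time +
    ifelse(is.na(scr_events$dur_s), 0L, scr_events$dur_s)
  t_end <- start_time
  last_rows <- !duplicated(idx, fromLast = TRUE)
  t_end[idx[last_rows]] <- t_resp[last_rows]

  # flowsheet -----------------------------------------------------------------
  fs_rows <- list()
  need_q12 <- documented | is_support
  if (any(need_q12)) {
    q1_val <- ifelse(patients$smoking_status[need_q12] == "current",
                     "Within the past 7 days", "More than 30 days ago")
    fs_rows$q1 <- tibble::tibble(
      encounter_id = encounter_id[need_q12], flowsheet_name = "Q1",
      flowsheet_value = q1_val, recorded_time = t_end[need_q12] + 60)
    fs_rows$q2 <- tibble::tibble(
      encounter_id = encounter_id[need_q12], flowsheet_name = "Q2",
      flowsheet_value = "Yes", recorded_time = t_end[need_q12] + 120)
  }
  if (any(documented)) {
    fs_rows$q3 <- tibble::tibble(
      encounter_id = encounter_id[documented], flowsheet_name = "Q3",
      flowsheet_value = "Advice given", recorded_time = t_end[documented] + 180)
  }
  flowsheet <- dplyr::bind_rows(fs_rows)

  # support events -------------------------------------------------------------
  sup_events <- NULL
  if (m > 0) {
    kk <- seq_len(m)
    postponed <- kk > sup$discussed - sup$discussed_postponed &
      kk <= sup$discussed
    sup_extra <- integer(m)
    sup_extra[postponed] <- distribute_extras(sup$extra_firings,
                                              sup$discussed_postponed)
    sup_action_final <- dplyr::case_when(
      kk <= sup$ready_to_quit ~ "discussed_ready",
      kk <= sup$discussed ~ "discussed_not_ready",
      TRUE ~ "not_discussed"
    )
    n_inst2 <- 1L + sup_extra
    idx2 <- rep(kk, n_inst2)
    k2 <- sequence(n_inst2)
    is_defer2 <- k2 < n_inst2[idx2]
    action2 <- ifelse(is_defer2, "defer", sup_action_final[idx2])
    dur2 <- dplyr::case_when(
      action2 == "defer" & k2 == 1 ~ as.integer(dur$support_postpone),
      action2 == "defer" ~ 0L,
      action2 %in% c("discussed_ready", "discussed_not_ready") ~
        as.integer(dur$support_complete),
      TRUE ~ as.integer(dur$other)
    )
    signed2 <- rep(NA_character_, length(idx2))
    signed2[!is_defer2 & idx2 <= sup$referral] <- "REF-TOBACCO"
    sup_events <- build_fixed_events(
      idx = idx2, k = k2, n_inst = n_inst2, dur_s = dur2, action = action2,
      interruptive = rep(TRUE, m), first_time = t_end[kk] + 300,
      encounter_id = encounter_id[kk], patient_id = patient_id[kk],
      kind = "support", signed = signed2
    )
  }

  events <- dplyr::bind_rows(scr_events, sup_events) |>
    dplyr::select(-"dur_s")
  list(patients = patients, encounters = encounters, events = events,
       flowsheet = flowsheet)
}

# shared event assembly for the expander: fixed durations, timer refires
build_fixed_events <- function(idx, k, n_inst, dur_s, action, interruptive,
                               first_time, encounter_id, patient_id, kind,
                               signed) {
  prefix <- if (kind == "screening") "SCR" else "SUP"
  gap <- ifelse(is.na(dur_s), 0L, dur_s) + 600
  offset <- stats::ave(gap, idx, FUN = function(g) {
    c(0, utils::head(cumsum(g), -1))
  })
  firing_time <- first_time[idx] + offset
  response_time <- firing_time + dur_s
  trigger <- ifelse(!interruptive[idx], "noninterruptive_display",
                    ifelse(k == 1, "chart_open", "timer_refire"))
  label_of <- stats::setNames(names(default_vocabulary()),
                              default_vocabulary())
  alert_id <- paste0(prefix, "-", encounter_id[idx])
  tibble::tibble(
    alert_id = alert_id,
    alert_instance_id = sprintf("%s-%02d", alert_id, k),
    alert_name = kind,
    encounter_id = encounter_id[idx],
    patient_id = patient_id[idx],
    firing_time = firing_time,
    response_time = response_time,
    triggering_condition = trigger,
    subsequent_action = ifelse(action == "no_response", "none",
                               "acknowledge_override_warning"),
    override_reason = ifelse(action == "no_response", NA_character_,
                             unname(label_of[action])),
    signed_order = if (is.null(signed)) NA_character_ else signed,
    dur_s = dur_s
  )
}
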