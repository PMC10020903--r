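# Stochastic event-log simulator with a per-encounter ground-truth ledger.
#
# The generator emulates the alert logic of a two-alert tobacco-cessation
# CDS program: a screening alert fires for encounters of current or
# unknown-status smokers; a support alert fires only when the screening
# result is positive (current smoker) and the screener questions are
# documented; interruptive alerts refire after the postpone interval.

#' Default encounter-type mix for the simulator
#'
#' @return Tibble with columns `type`, `relevance`, `prob`.
#' @export
default_encounter_types <- function() {
  tibble::tibble(
    type = c("office_visit", "initial_consult", "follow_up", "lab_visit",
             "treatment_visit"),
    relevance = c("relevant", "relevant", "relevant", "less_relevant",
                  "less_relevant"),
    prob = c(0.45, 0.12, 0.23, 0.1, 0.1)
  )
}

#' Default clinic layout for the simulator
#'
#' Seven cancer clinics mirroring a multi-clinic implementation: three
#' medical-oncology, three radiation-oncology and one survivorship clinic;
#' two clinics implement the screening alert only, five implement both.
#' Encounter volumes are scaled so that roughly five thousand screening
#' alerts fire over 12 months under the default smoking-status mix.
#'
#' @return Tibble with columns `clinic_id`, `name`, `go_live_date`,
#'   `screening_alert`, `support_alert`, `n_encounters`.
#' @export
default_sim_clinics <- function() {
  tibble::tibble(
    clinic_id = c("M1", "M2", "M3", "R1", "R2", "R3", "S"),
    name = c("Medical oncology 1", "Medical oncology 2", "Medical oncology 3",
             "Radiation oncology 1", "Radiation oncology 2",
             "Radiation oncology 3", "Cancer survivorship"),
    go_live_date = as.Date(c("2019-06-03", "2019-07-01", "2019-08-05",
                             "2019-09-02", "2019-10-07", "2020-01-06",
                             "2020-02-03")),
    screening_alert = TRUE,
    support_alert = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    n_encounters = c(2700L, 2000L, 6700L, 1350L, 500L, 3350L, 600L)
  )
}

#' Simulator configuration
#'
#' Collects the behavioral parameters of the event-log generator. Defaults
#' encode the monitored program's observed conditions: 55% of fired
#' screening alerts acknowledged complete, documentation following
#' acknowledgment often skipped (the navigator-bypass gap), 87.3% of support
#' alerts handled without postponing, 59.6% with a documented discussion,
#' about 20% of discussed patients ready to quit and 17% of those referred;
#' interruptive alerts refire 600 s after a postpone.
#'
#' @param clinics Clinic table, see [default_sim_clinics()].
#' @param encounter_types Encounter-type mix, see
#'   [default_encounter_types()].
#' @param smoking_status_dist,sex_dist,race_dist Named probability vectors
#'   over the respective enum levels.
#' @param patients_per_encounter Ratio of distinct patients to encounters.
#' @param p_interruptive Probability a fired alert episode is interruptive.
#' @param p_ack_complete,p_not_appropriate,p_defer_only Screening episode
#'   disposition probabilities (remainder: no response).
#' @param p_document_given_ack,p_document_given_not_ack Probability the
#'   screener questions are documented in the flowsheet.
#' @param p_stop_screening Geometric stopping probability for the number of
#'   defers preceding a screening response (mean defers = (1-p)/p).
#' @param p_support_postpone Probability a support episode is postponed at
#'   least once before the response.
#' @param p_stop_support Geometric stopping probability for additional
#'   support defers beyond the first.
#' @param p_discussed Probability the support response documents a
#'   discussion (readiness assessed).
#' @param p_ready_given_discussed,p_referral_given_ready Conditional
#'   probabilities for readiness to quit and a signed referral order.
#' @param p_chart_reopen Probability a refire is a chart reopen rather than
#'   the postpone timer.
#' @param duration_mean_s Named vector of mean handling seconds per action
#'   class (`screening_complete`, `screening_postpone`, `support_complete`,
#'   `support_postpone`, `other`).
#' @param duration_sdlog Log-scale SD of the lognormal duration model.
#' @param refire_interval_s Seconds between a postpone and the refire
#'   (default 600 = 10 minutes).
#' @param max_defers Cap on defers per episode (bounds episode length).
#' @param required_questions Screener question names emitted to the
#'   flowsheet.
#' @param seed Default RNG seed used by [simulate_alerts()].
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(clinics = default_sim_clinics(),
                       encounter_types = default_encounter_types(),
                       smoking_status_dist = c(current = 0.13, former = 0.25,
                                               never = 0.45, unknown = 0.17),
                       sex_dist = c(female = 0.55, male = 0.45),
                       race_dist = c(african_american = 0.18, white = 0.76,
                                     other = 0.05, unknown = 0.01),
                       patients_per_encounter = 0.7,
                       p_interruptive = 0.85,
                       p_ack_complete = 0.55,
                       p_not_appropriate = 0.10,
                       p_defer_only = 0.05,
                       p_document_given_ack = 0.58,
                       p_document_given_not_ack = 0.02,
                       p_stop_screening = 0.37,
                       p_support_postpone = 0.127,
                       p_stop_support = 0.48,
                       p_discussed = 0.596,
                       p_ready_given_discussed = 0.20,
                       p_referral_given_ready = 0.17,
                       p_chart_reopen = 0.25,
                       duration_mean_s = c(screening_complete = 53,
                                           screening_postpone = 52,
                                           support_complete = 50,
                                           support_postpone = 67,
                                           other = 12),
                       duration_sdlog = 0.4,
                       refire_interval_s = 600,
                       max_defers = 20,
                       required_questions = c("Q1", "Q2", "Q3"),
                       seed = 20190603) {
  config <- list(clinics = tibble::as_tibble(clinics),
                 encounter_types = tibble::as_tibble(encounter_types),
                 smoking_status_dist = smoking_status_dist,
                 sex_dist = sex_dist, race_dist = race_dist,
                 patients_per_encounter = patients_per_encounter,
                 p_interruptive = p_interruptive,
                 p_ack_complete = p_ack_complete,
                 p_not_appropriate = p_not_appropriate,
                 p_defer_only = p_defer_only,
                 p_document_given_ack = p_document_given_ack,
                 p_document_given_not_ack = p_document_given_not_ack,
                 p_stop_screening = p_stop_screening,
                 p_support_postpone = p_support_postpone,
                 p_stop_support = p_stop_support,
                 p_discussed = p_discussed,
                 p_ready_given_discussed = p_ready_given_discussed,
                 p_referral_given_ready = p_referral_given_ready,
                 p_chart_reopen = p_chart_reopen,
                 duration_mean_s = duration_mean_s,
                 duration_sdlog = duration_sdlog,
                 refire_interval_s = refire_interval_s,
                 max_defers = max_defers,
                 required_questions = required_questions,
                 seed = seed)
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  probs <- config[grepl("^p_", names(config))]
  bad <- names(probs)[vapply(probs, function(p) {
    !is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1
  }, TRUE)]
  if (length(bad) > 0) {
    abort_config(paste0("probabilities outside [0,1]: ",
                        paste(bad, collapse = ", ")))
  }
  total <- config$p_ack_complete + config$p_not_appropriate +
    config$p_defer_only
  if (total > 1) {
    abort_config("p_ack_complete + p_not_appropriate + p_defer_only exceeds 1")
  }
  for (nm in c("smoking_status_dist", "sex_dist", "race_dist")) {
    dist <- config[[nm]]
    if (any(dist < 0) || sum(dist) <= 0) {
      abort_config(paste0(nm, " must be a non-negative distribution"))
    }
  }
  if (any(config$encounter_types$prob < 0) ||
      sum(config$encounter_types$prob) <= 0) {
    abort_config("encounter_types$prob must be a non-negative distribution")
  }
  if (!all(config$encounter_types$relevance %in% RELEVANCE_LEVELS)) {
    abort_config("encounter_types$relevance must be relevant/less_relevant")
  }
  if (config$refire_interval_s <= 0) {
    abort_config("refire_interval_s must be positive")
  }
  if (config$max_defers < 1) abort_config("max_defers must be >= 1")
  needed <- c("screening_complete", "screening_postpone", "support_complete",
              "support_postpone", "other")
  if (!all(needed %in% names(config$duration_mean_s)) ||
      any(config$duration_mean_s[needed] <= 0)) {
    abort_config("duration_mean_s must name positive means for all classes")
  }
  cl_cols <- c("clinic_id", "name", "go_live_date", "screening_alert",
               "support_alert", "n_encounters")
  missing <- setdiff(cl_cols, names(config$clinics))
  if (length(missing) > 0) {
    abort_config(paste0("clinics table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  invisible(config)
}

sample_levels <- function(dist, n) {
  names(dist)[sample.int(length(dist), n, replace = TRUE, prob = dist)]
}

lognormal_s <- function(class, config) {
  mu <- log(config$duration_mean_s[class]) - config$duration_sdlog^2 / 2
  pmax(1L, as.integer(round(stats::rlnorm(length(class), meanlog = mu,
                                          sdlog = config$duration_sdlog))))
}

#' Simulate an alert event log with ground truth
#'
#' Generates patients, encounters, flowsheet documentation and alert events
#' under the configured behavior model, together with a per-encounter
#' ground-truth ledger recording the true disposition of every outcome flag
#' and handling-time sum. The ledger is written at generation time from the
#' behavioral draws themselves, so it is an oracle for the episode builder
#' and metrics engine. The same seed yields an identical dataset.
#'
#' Alert logic: the screening alert fires only for encounters whose patient
#' is a current smoker or has unknown status (at clinics implementing it);
#' the support alert fires only when the patient is a current smoker and the
#' screener questions were documented, after the documentation time;
#' postponed interruptive instances refire `refire_interval_s` seconds after
#' the postpone (as a timer refire or a simulated chart reopen).
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List of class `alert_simulation`: `dataset` (an
#'   [alert_dataset()]) and `ground_truth` (tibble, one row per encounter in
#'   which an alert fired, columns matching [rollup_encounters()] output).
#' @export
simulate_alerts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)

  cl <- config$clinics
  n_total <- sum(cl$n_encounters)
  n_pat <- max(1L, ceiling(n_total * config$patients_per_encounter))
  patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n_pat)),
    sex = sample_levels(config$sex_dist, n_pat),
    race = sample_levels(config$race_dist, n_pat),
    smoking_status = sample_levels(config$smoking_status_dist, n_pat)
  )

  enc <- tibble::tibble(
    clinic_id = rep(cl$clinic_id, cl$n_encounters),
    go_live_date = rep(cl$go_live_date, cl$n_encounters),
    screening_on = rep(cl$screening_alert, cl$n_encounters),
    support_on = rep(cl$support_alert, cl$n_encounters)
  )
  enc$encounter_id <- sprintf("E%06d", seq_len(n_total))
  enc$patient_id <- patients$patient_id[sample.int(n_pat, n_total,
                                                   replace = TRUE)]
  enc <- dplyr::left_join(enc, patients, by = "patient_id")
  et <- config$encounter_types
  ti <- sample.int(nrow(et), n_total, replace = TRUE, prob = et$prob)
  enc$encounter_type <- et$type[ti]
  enc$relevance <- et$relevance[ti]
  enc$start_time <- as.POSIXct(enc$go_live_date, tz = "UTC") +
    (sample.int(360, n_total, replace = TRUE) - 1) * 86400 +
    8 * 3600 + sample.int(8 * 3600, n_total, replace = TRUE)

  enc$screening_fired <- enc$screening_on &
    enc$smoking_status %in% c("current", "unknown")

  scr <- enc[enc$screening_fired, ]
  ns <- nrow(scr)
  scr$interruptive <- stats::runif(ns) < config$p_interruptive
  p_rest <- 1 - config$p_ack_complete - config$p_not_appropriate -
    config$p_defer_only
  scr$category <- sample_levels(c(ack = config$p_ack_complete,
                                  not_appropriate = config$p_not_appropriate,
                                  defer_only = config$p_defer_only,
                                  no_response = p_rest), ns)
  g1 <- stats::rgeom(ns, config$p_stop_screening)
  g2 <- stats::rgeom(ns, config$p_stop_screening)
  scr$n_pre <- ifelse(scr$category %in% c("ack", "not_appropriate") &
                        scr$interruptive,
                      pmin(g1, config$max_defers), 0L)
  scr$n_def_only <- ifelse(scr$category == "defer_only",
                           ifelse(scr$interruptive,
                                  pmin(1L + g2, config$max_defers), 1L), 0L)
  scr$n_inst <- dplyr::case_when(
    scr$category == "no_response" ~ 1L,
    scr$category == "defer_only" ~ as.integer(scr$n_def_only),
    TRUE ~ as.integer(scr$n_pre) + 1L
  )
  u_doc <- stats::runif(ns)
  scr$documented <- ifelse(scr$category == "ack",
                           u_doc < config$p_document_given_ack,
                           u_doc < config$p_document_given_not_ack)

  scr_ev <- expand_sim_events(scr, kind = "screening", config = config,
                              first_time = scr$start_time)

  # flowsheet rows for documented encounters, after the screening episode
  scr_end <- episode_end_times(scr_ev, scr)
  doc <- scr[scr$documented, ]
  doc_end <- scr_end[scr$documented]
  q <- config$required_questions
  flowsheet <- tibble::tibble(
    encounter_id = rep(doc$encounter_id, each = length(q)),
    flowsheet_name = rep(q, times = nrow(doc)),
    flowsheet_value = as.vector(vapply(seq_len(nrow(doc)), function(i) {
      q1 <- if (doc$smoking_status[i] == "current") "Within the past 7 days"
            else "More than 30 days ago"
      c(q1, "Yes", "Advice given")[seq_along(q)]
    }, character(length(q)))),
    recorded_time = rep(doc_end, each = length(q)) + 60 * seq_along(q)
  )

  # support alert: positive screen (current smoker) + documented screener
  scr$support_fired <- scr$support_on & scr$smoking_status == "current" &
    scr$documented
  sup <- scr[scr$support_fired, ]
  nsup <- nrow(sup)
  sup$interruptive <- rep(TRUE, nsup)
  sup$postponed <- stats::runif(nsup) < config$p_support_postpone
  sup$n_pre <- ifelse(sup$postponed,
                      pmin(1L + stats::rgeom(nsup, config$p_stop_support),
                           config$max_defers), 0L)
  u_disc <- stats::runif(nsup)
  sup$discussed <- u_disc < config$p_discussed
  sup$ready <- sup$discussed &
    stats::runif(nsup) < config$p_ready_given_discussed
  sup$referral <- sup$ready &
    stats::runif(nsup) < config$p_referral_given_ready
  sup$category <- dplyr::case_when(
    sup$ready ~ "discussed_ready",
    sup$discussed ~ "discussed_not_ready",
    TRUE ~ "not_discussed"
  )
  sup$n_inst <- as.integer(sup$n_pre) + 1L
  sup_start <- scr_end[scr$support_fired] + 60 * length(q) + 120
  sup_ev <- expand_sim_events(sup, kind = "support", config = config,
                              first_time = sup_start)

  events <- dplyr::bind_rows(scr_ev$events, sup_ev$events) |>
    dplyr::arrange(.data$alert_id, .data$firing_time, .data$alert_instance_id)

  d <- alert_dataset(
    patients = patients,
    encounters = enc[, c("encounter_id", "patient_id", "clinic_id",
                         "encounter_type", "start_time")],
    clinics = cl[, c("clinic_id", "name", "go_live_date", "screening_alert",
                     "support_alert")],
    alert_events = events,
    flowsheet = flowsheet
  )

  truth <- sim_ground_truth(scr, sup, scr_ev, sup_ev, config)
  structure(list(dataset = d, ground_truth = truth,
                 config = config, seed = seed),
            class = "alert_simulation")
}

# expand per-episode draws into instance-level events; returns the events
# plus per-episode duration sums for the ground-truth ledger
expand_sim_events <- function(df, kind, config, first_time) {
  prefix <- if (kind == "screening") "SCR" else "SUP"
  n <- nrow(df)
  if (n == 0) {
    return(list(
      events = tibble::tibble(alert_id = character(0),
                              alert_instance_id = character(0),
                              alert_name = character(0),
                              encounter_id = character(0),
                              patient_id = character(0),
                              firing_time = as.POSIXct(character(0), tz = "UTC"),
                              response_time = as.POSIXct(character(0), tz = "UTC"),
                              triggering_condition = character(0),
                              subsequent_action = character(0),
                              override_reason = character(0),
                              signed_order = character(0)),
      sums = tibble::tibble(encounter_id = character(0),
                            complete_time_s = integer(0),
                            complete_k = integer(0),
                            postpone_time_s = integer(0),
                            postpone_k = integer(0))))
  }
  idx <- rep(seq_len(n), df$n_inst)
  k <- sequence(df$n_inst)
  n_ev <- length(idx)
  category <- df$category[idx]
  n_pre <- df$n_pre[idx]
  n_inst <- df$n_inst[idx]
  interruptive <- df$interruptive[idx]

  is_defer <- if (kind == "screening") {
    (category %in% c("ack", "not_appropriate") & k <= n_pre) |
      category == "defer_only"
  } else {
    k <= n_pre
  }
  is_final <- k == n_inst & !is_defer & category != "no_response"
  action <- dplyr::case_when(
    is_defer ~ "defer",
    is_final & category == "ack" ~ "ack_complete_screening",
    is_final & category %in% c("not_appropriate", "discussed_ready",
                               "discussed_not_ready", "not_discussed") ~
      category,
    TRUE ~ "no_response"
  )
  dur_class <- dplyr::case_when(
    action == "defer" & kind == "screening" ~ "screening_postpone",
    action == "defer" ~ "support_postpone",
    action == "ack_complete_screening" ~ "screening_complete",
    action %in% c("discussed_ready", "discussed_not_ready") ~
      "support_complete",
    action == "no_response" ~ NA_character_,
    TRUE ~ "other"
  )
  dur <- rep(NA_integer_, n_ev)
  has_dur <- !is.na(dur_class)
  dur[has_dur] <- lognormal_s(dur_class[has_dur], config)

  # firing time of instance k: previous response + refire interval
  gap <- ifelse(is.na(dur), 0L, dur) + config$refire_interval_s
  offset <- stats::ave(gap, idx, FUN = function(g) {
    c(0, utils::head(cumsum(g), -1))
  })
  firing_time <- first_time[idx] + offset
  response_time <- firing_time + dur

  reopen <- stats::runif(n_ev) < config$p_chart_reopen
  trigger <- ifelse(!interruptive, "noninterruptive_display",
                    ifelse(k == 1, "chart_open",
                           ifelse(reopen, "chart_reopen", "timer_refire")))
  label_of <- stats::setNames(names(default_vocabulary()),
                              default_vocabulary())
  override <- ifelse(action == "no_response", NA_character_,
                     unname(label_of[action]))
  alert_id <- paste0(prefix, "-", df$encounter_id[idx])
  signed <- rep(NA_character_, n_ev)
  if (kind == "support") {
    signed[is_final & df$referral[idx]] <- "REF-TOBACCO"
  }
  events <- tibble::tibble(
    alert_id = alert_id,
    alert_instance_id = sprintf("%s-%02d", alert_id, k),
    alert_name = kind,
    encounter_id = df$encounter_id[idx],
    patient_id = df$patient_id[idx],
    firing_time = firing_time,
    response_time = response_time,
    triggering_condition = trigger,
    subsequent_action = ifelse(action == "no_response", "none",
                               "acknowledge_override_warning"),
    override_reason = override,
    signed_order = signed
  )
  sums <- tibble::tibble(encounter_id = df$encounter_id[idx],
                         dur = dur, action = action) |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::summarise(
      complete_time_s = sum_or_na(.data$dur[.data$action %in%
                                              responding_actions()]),
      complete_k = sum(.data$action %in% responding_actions() &
                         !is.na(.data$dur)),
      postpone_time_s = sum_or_na(.data$dur[.data$action == "defer"]),
      postpone_k = sum(.data$action == "defer" & !is.na(.data$dur)),
      .groups = "drop")
  list(events = events, sums = sums)
}

episode_end_times <- function(ev_out, df) {
  ends <- ev_out$events |>
    dplyr::mutate(t = dplyr::coalesce(.data$response_time,
                                      .data$firing_time)) |>
    dplyr::summarise(t_end = max(.data$t), .by = "encounter_id")
  lookup <- stats::setNames(ends$t_end, ends$encounter_id)
  out <- lookup[df$encounter_id]
  attributes(out) <- attributes(ends$t_end)
  out
}

sim_ground_truth <- function(scr, sup, scr_ev, sup_ev, config) {
  truth <- tibble::tibble(
    encounter_id = scr$encounter_id,
    clinic_id = scr$clinic_id,
    window_index = window_index(scr$start_time, scr$go_live_date),
    encounter_type = scr$encounter_type,
    relevance = scr$relevance,
    sex = scr$sex,
    race = scr$race,
    screening_fired = TRUE,
    screening_ack_completed = scr$category == "ack",
    screening_documented = scr$documented,
    screening_deferred_any = scr$n_pre > 0 | scr$category == "defer_only",
    screening_not_appropriate = scr$category == "not_appropriate",
    support_fired = scr$support_fired
  )
  sup_flags <- tibble::tibble(
    encounter_id = sup$encounter_id,
    support_no_postpone = !sup$postponed,
    support_deferred_any = sup$postponed,
    support_discussed = sup$discussed,
    support_ready_to_quit = sup$ready,
    support_referral_ordered = sup$referral
  )
  truth <- dplyr::left_join(truth, sup_flags, by = "encounter_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("support_"),
                                ~ dplyr::coalesce(.x, FALSE)))
  scr_sums <- dplyr::rename_with(scr_ev$sums, ~ paste0("screening_", .x),
                                 -"encounter_id")
  sup_sums <- dplyr::rename_with(sup_ev$sums, ~ paste0("support_", .x),
                                 -"encounter_id")
  truth <- truth |>
    dplyr::left_join(scr_sums, by = "encounter_id") |>
    dplyr::left_join(sup_sums, by = "encounter_id") |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_k"),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::arrange(.data$encounter_id)
  truth
}

#' Check the conditional support-alert firing logic
#'
#' The support alert may fire only when the encounter's screening result is
#' positive (patient a current smoker) and both leading screener questions
#' were documented before the support alert first fired. Returns the
#' violations found in a dataset; the simulator's output always passes by
#' construction.
#'
#' @param d An [alert_dataset()].
#' @param required_first_questions Screener questions that must precede a
#'   support firing (default Q1, Q2).
#' @return Tibble of violations (`rule`, `alert_id`, `encounter_id`,
#'   `message`); zero rows when the logic holds.
#' @export
conditional_firing_check <- function(d,
                                     required_first_questions = c("Q1", "Q2")) {
  stopifnot(inherits(d, "alert_dataset"))
  sup <- d$alert_events[d$alert_events$alert_name == "support", ]
  if (nrow(sup) == 0) {
    return(tibble::tibble(rule = character(0), alert_id = character(0),
                          encounter_id = character(0), message = character(0)))
  }
  first <- sup |>
    dplyr::summarise(first_firing = min(.data$firing_time),
                     encounter_id = .data$encounter_id[1],
                     .by = "alert_id") |>
    dplyr::left_join(d$encounters[, c("encounter_id", "patient_id")],
                     by = "encounter_id") |>
    dplyr::left_join(d$patients[, c("patient_id", "smoking_status")],
                     by = "patient_id")
  v <- list()
  bad <- first[is.na(first$smoking_status) |
                 first$smoking_status != "current", ]
  if (nrow(bad) > 0) {
    v[[length(v) + 1]] <- tibble::tibble(
      rule = "support_requires_positive_screen",
      alert_id = bad$alert_id, encounter_id = bad$encounter_id,
      message = paste0("support alert fired for a patient with smoking ",
                       "status '", bad$smoking_status, "'"))
  }
  fs <- d$flowsheet[!is.na(d$flowsheet$flowsheet_value) &
                      nzchar(d$flowsheet$flowsheet_value), ]
  for (qname in required_first_questions) {
    qrows <- fs[fs$flowsheet_name == qname, ]
    qtime <- qrows |>
      dplyr::summarise(q_time = suppressWarnings(min(.data$recorded_time)),
                       .by = "encounter_id")
    chk <- dplyr::left_join(first, qtime, by = "encounter_id")
    bad <- chk[is.na(chk$q_time) | chk$q_time > chk$first_firing, ]
    if (nrow(bad) > 0) {
      v[[length(v) + 1]] <- tibble::tibble(
        rule = "support_requires_documented_screener",
        alert_id = bad$alert_id, encounter_id = bad$encounter_id,
        message = paste0(qname, " not documented before the support alert ",
                         "fired"))
    }
  }
  if (length(v) == 0) {
    tibble::tibble(rule = character(0), alert_id = character(0),
                   encounter_id = character(0), message = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}

#' Draw a random simulator configuration
#'
#' Used by property tests: small clinic layouts and behavior probabilities
#' drawn over wide but valid ranges, so pipeline/ground-truth equivalence is
#' exercised across the configuration space.
#'
#' @param seed RNG seed controlling the draw.
#' @return A [sim_config()].
#' @export
random_sim_config <- function(seed) {
  set.seed(seed)
  k <- sample(2:3, 1)
  clinics <- tibble::tibble(
    clinic_id = paste0("C", seq_len(k)),
    name = paste("Clinic", seq_len(k)),
    go_live_date = as.Date("2020-01-06") + sample(0:180, k, replace = TRUE),
    screening_alert = TRUE,
    support_alert = c(TRUE, stats::runif(k - 1) < 0.7),
    n_encounters = sample(60:200, k, replace = TRUE)
  )
  p_ack <- stats::runif(1, 0.2, 0.8)
  p_na <- stats::runif(1, 0, 0.15)
  p_def <- stats::runif(1, 0, 0.1)
  sim_config(
    clinics = clinics,
    p_interruptive = stats::runif(1, 0.5, 1),
    p_ack_complete = p_ack,
    p_not_appropriate = p_na,
    p_defer_only = p_def,
    p_document_given_ack = stats::runif(1, 0.3, 1),
    p_document_given_not_ack = stats::runif(1, 0, 0.1),
    p_stop_screening = stats::runif(1, 0.3, 0.8),
    p_support_postpone = stats::runif(1, 0, 0.4),
    p_stop_support = stats::runif(1, 0.3, 0.8),
    p_discussed = stats::runif(1, 0.2, 0.9),
    p_ready_given_discussed = stats::runif(1, 0, 0.5),
    p_referral_given_ready = stats::runif(1, 0, 0.5),
    seed = sample.int(.Machine$integer.max, 1)
  )
}
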