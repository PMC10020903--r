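# Episode reconstruction: from instance-level alert events to per-alert
# episodes and per-encounter outcomes.

#' 3-month window index relative to a clinic's go-live date
#'
#' Window `k` (k = 0..n_windows-1) covers the half-open calendar-month
#' interval `[go_live + 3k months, go_live + 3(k+1) months)`. Times at or
#' beyond `3 * n_windows` months (or before go-live) get `NA`: they are
#' excluded from windowed outputs but retained in the dataset.
#'
#' @param time POSIXct vector.
#' @param go_live Date vector (recycled) of go-live dates.
#' @param n_windows Number of windows covering the monitoring period
#'   (default 4, i.e. 12 months).
#' @return Integer vector of window indices, `NA` when out of window.
#' @export
window_index <- function(time, go_live, n_windows = 4) {
  g <- as.POSIXct(as.Date(go_live), tz = "UTC")
  m <- lubridate::interval(g, time) %/% lubridate::period(months = 1)
  w <- m %/% 3L
  w[is.na(time) | time < g | m >= 3L * n_windows] <- NA_integer_
  as.integer(w)
}

#' Classify an alert episode's modality
#'
#' An episode is interruptive if any of its instances interrupted the
#' provider: fired on chart open or reopen, or refired on the postpone
#' timer. Episodes whose every instance sat passively in the BPA section
#' are noninterruptive. Mixed episodes are classed interruptive because any
#' interruption exposes the provider to interruption burden.
#'
#' @param triggering_condition Character vector of the episode's instance
#'   trigger conditions.
#' @return `"interruptive"` or `"noninterruptive"`.
#' @export
determine_modality <- function(triggering_condition) {
  if (length(triggering_condition) == 0) {
    stop("determine_modality() needs at least one instance")
  }
  if (any(triggering_condition %in%
            c("chart_open", "chart_reopen", "timer_refire"))) {
    "interruptive"
  } else {
    "noninterruptive"
  }
}

#' Is screening documentation complete for an encounter?
#'
#' Documentation is complete when every required screener question has at
#' least one flowsheet row with a non-empty value, regardless of which alert
#' button was pressed.
#'
#' @param rows Flowsheet rows of one encounter (tibble with
#'   `flowsheet_name`, `flowsheet_value`).
#' @param required_questions Names of the required screener questions.
#' @return Logical scalar.
#' @export
documentation_complete <- function(rows, required_questions = c("Q1", "Q2", "Q3")) {
  answered <- unique(rows$flowsheet_name[!is.na(rows$flowsheet_value) &
                                           nzchar(rows$flowsheet_value)])
  all(required_questions %in% answered)
}

#' Reconstruct alert episodes from instance-level events
#'
#' Groups alert events by `alert_id` into episodes: all firings of one alert
#' within one encounter, from first firing to final disposition. Instances
#' are ordered by firing time (ties broken by ascending
#' `alert_instance_id`). Each instance gets a canonical action: the
#' vocabulary mapping of its trimmed `override_reason` when the provider
#' acknowledged the alert, `no_response` otherwise. The episode's final
#' action gives any responding (non-defer) action precedence over defers,
#' with the last responding action in time winning among responders.
#'
#' @param d A valid [alert_dataset()].
#' @param n_windows Number of 3-month windows (passed to [window_index()]).
#' @return Tibble with one row per episode: `alert_id`, `alert_kind`,
#'   `encounter_id`, `patient_id`, `clinic_id`, `window_index`,
#'   `first_firing_time`, `n_firings`, `modality`, `final_action`,
#'   `completed`, `responded`, `deferred_any`, `any_not_appropriate`,
#'   `any_discussed_ready`, `referral_ordered`, and per-episode handling
#'   sums `complete_time_s` / `postpone_time_s` (with instance counts
#'   `complete_k` / `postpone_k`). Sums are `NA` when no instance
#'   contributed.
#' @export
build_episodes <- function(d, n_windows = 4) {
  stopifnot(inherits(d, "alert_dataset"))
  ev <- d$alert_events
  if (nrow(ev) == 0) {
    return(empty_episode_table())
  }
  token <- trimws(ev$override_reason)
  acked <- ev$subsequent_action == "acknowledge_override_warning"
  unmapped <- unique(token[acked & !is.na(token) &
                             !(token %in% names(d$vocabulary))])
  if (length(unmapped) > 0) {
    abort_validation(paste0("override_reason token(s) not in vocabulary: ",
                            paste(unmapped, collapse = ", ")))
  }
  ev$canonical_action <- ifelse(acked, unname(d$vocabulary[token]),
                                "no_response")
  ev$duration_s <- as.integer(round(as.numeric(
    difftime(ev$response_time, ev$firing_time, units = "secs"))))
  ev$has_order <- !is.na(ev$signed_order) & nzchar(ev$signed_order)

  enc <- d$encounters[, c("encounter_id", "clinic_id", "start_time")]
  cl <- d$clinics[, c("clinic_id", "go_live_date")]
  ev <- ev |>
    dplyr::left_join(enc, by = "encounter_id") |>
    dplyr::left_join(cl, by = "clinic_id") |>
    dplyr::arrange(.data$alert_id, .data$firing_time, .data$alert_instance_id)

  responding <- responding_actions()
  episodes <- ev |>
    dplyr::group_by(.data$alert_id) |>
    dplyr::summarise(
      alert_kind = .data$alert_name[1],
      encounter_id = .data$encounter_id[1],
      patient_id = .data$patient_id[1],
      clinic_id = .data$clinic_id[1],
      start_time = .data$start_time[1],
      go_live_date = .data$go_live_date[1],
      first_firing_time = .data$firing_time[1],
      n_firings = dplyr::n(),
      modality = determine_modality(.data$triggering_condition),
      final_action = episode_final_action(.data$canonical_action),
      completed = any(.data$canonical_action %in%
                        completing_actions(.data$alert_name[1])),
      responded = any(.data$canonical_action %in% responding),
      deferred_any = any(.data$canonical_action == "defer"),
      any_not_appropriate = any(.data$canonical_action == "not_appropriate"),
      any_discussed_ready = any(.data$canonical_action == "discussed_ready"),
      referral_ordered = any(.data$has_order),
      complete_time_s = sum_or_na(
        .data$duration_s[.data$canonical_action %in% responding]),
      complete_k = sum(.data$canonical_action %in% responding &
                         !is.na(.data$duration_s)),
      postpone_time_s = sum_or_na(
        .data$duration_s[.data$canonical_action == "defer"]),
      postpone_k = sum(.data$canonical_action == "defer" &
                         !is.na(.data$duration_s)),
      .groups = "drop"
    )
  episodes$window_index <- window_index(episodes$start_time,
                                        episodes$go_live_date, n_windows)
  episodes |>
    dplyr::select(-"start_time", -"go_live_date") |>
    dplyr::relocate("window_index", .after = "clinic_id")
}

# final action of a time-ordered episode: last responding (non-defer,
# non-no_response) action wins; otherwise defer if ever deferred; otherwise
# no_response
episode_final_action <- function(actions) {
  resp <- which(actions %in% responding_actions())
  if (length(resp) > 0) return(actions[resp[length(resp)]])
  if (any(actions == "defer")) return("defer")
  "no_response"
}

sum_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_integer_ else as.integer(sum(x))
}

empty_episode_table <- function() {
  tibble::tibble(alert_id = character(0), alert_kind = character(0),
                 encounter_id = character(0), patient_id = character(0),
                 clinic_id = character(0), window_index = integer(0),
                 first_firing_time = as.POSIXct(character(0), tz = "UTC"),
                 n_firings = integer(0), modality = character(0),
                 final_action = character(0), completed = logical(0),
                 responded = logical(0), deferred_any = logical(0),
                 any_not_appropriate = logical(0),
                 any_discussed_ready = logical(0),
                 referral_ordered = logical(0),
                 complete_time_s = integer(0), complete_k = integer(0),
                 postpone_time_s = integer(0), postpone_k = integer(0))
}

#' Roll alert episodes up to per-encounter outcomes
#'
#' Produces one row per encounter in which at least one studied alert fired,
#' carrying the encounter's clinic, 3-month window, relevance class and
#' patient demographics together with the screening and support dispositions
#' the metrics consume. Handling-time fields sum instance durations within
#' the encounter: `*_complete_time_s` over instances with a responding
#' (non-defer) action, `*_postpone_time_s` over defer instances; an
#' encounter can contribute to both. Screening documentation is evaluated
#' from the encounter's flowsheet rows regardless of which alert button was
#' pressed, so an encounter can be acknowledged-complete yet undocumented.
#'
#' @param episodes Episode table from [build_episodes()].
#' @param d The [alert_dataset()] the episodes were built from.
#' @param relevance_map Named character vector (encounter type ->
#'   `relevant`/`less_relevant`); must cover every encounter type present.
#' @param required_questions Screener questions required for complete
#'   documentation.
#' @return Tibble with one row per encounter with any alert firing.
#' @export
rollup_encounters <- function(episodes, d,
                              relevance_map = example_relevance_map(),
                              required_questions = c("Q1", "Q2", "Q3")) {
  stopifnot(inherits(d, "alert_dataset"))
  enc_ids <- unique(episodes$encounter_id)
  enc <- d$encounters[d$encounters$encounter_id %in% enc_ids, ]
  unmapped <- setdiff(unique(enc$encounter_type), names(relevance_map))
  if (length(unmapped) > 0) {
    abort_config(paste0("encounter type(s) missing from relevance map: ",
                        paste(unmapped, collapse = ", ")))
  }

  doc <- d$flowsheet |>
    dplyr::filter(.data$flowsheet_name %in% required_questions,
                  !is.na(.data$flowsheet_value),
                  nzchar(.data$flowsheet_value)) |>
    dplyr::distinct(.data$encounter_id, .data$flowsheet_name) |>
    dplyr::count(.data$encounter_id, name = "n_answered")

  kind_rollup <- function(kind) {
    episodes |>
      dplyr::filter(.data$alert_kind == kind) |>
      dplyr::group_by(.data$encounter_id) |>
      dplyr::summarise(
        fired = TRUE,
        completed = any(.data$completed),
        responded = any(.data$responded),
        deferred_any = any(.data$deferred_any),
        not_appropriate = any(.data$any_not_appropriate),
        discussed_ready = any(.data$any_discussed_ready),
        referral = any(.data$referral_ordered),
        complete_time_s = sum_or_na(.data$complete_time_s),
        complete_k = sum(.data$complete_k),
        postpone_time_s = sum_or_na(.data$postpone_time_s),
        postpone_k = sum(.data$postpone_k),
        .groups = "drop"
      )
  }
  scr <- kind_rollup("screening")
  sup <- kind_rollup("support")

  out <- enc |>
    dplyr::left_join(d$patients[, c("patient_id", "sex", "race")],
                     by = "patient_id") |>
    dplyr::left_join(d$clinics[, c("clinic_id", "go_live_date")],
                     by = "clinic_id") |>
    dplyr::mutate(
      window_index = window_index(.data$start_time, .data$go_live_date),
      relevance = unname(relevance_map[.data$encounter_type])
    ) |>
    dplyr::left_join(doc, by = "encounter_id") |>
    dplyr::left_join(scr, by = "encounter_id") |>
    dplyr::left_join(sup, by = "encounter_id",
                     suffix = c("_scr", "_sup"))

  false_if_na <- function(x) !is.na(x) & x
  tibble::tibble(
    encounter_id = out$encounter_id,
    clinic_id = out$clinic_id,
    window_index = out$window_index,
    encounter_type = out$encounter_type,
    relevance = out$relevance,
    sex = out$sex,
    race = out$race,
    screening_fired = false_if_na(out$fired_scr),
    screening_ack_completed = false_if_na(out$completed_scr),
    screening_documented = !is.na(out$n_answered) &
      out$n_answered >= length(required_questions),
    screening_deferred_any = false_if_na(out$deferred_any_scr),
    screening_not_appropriate = false_if_na(out$not_appropriate_scr),
    support_fired = false_if_na(out$fired_sup),
    support_no_postpone = false_if_na(out$responded_sup) &
      !false_if_na(out$deferred_any_sup),
    support_deferred_any = false_if_na(out$deferred_any_sup),
    support_discussed = false_if_na(out$completed_sup),
    support_ready_to_quit = false_if_na(out$discussed_ready_sup),
    support_referral_ordered = false_if_na(out$referral_sup),
    screening_complete_time_s = out$complete_time_s_scr,
    screening_complete_k = dplyr::coalesce(out$complete_k_scr, 0L),
    screening_postpone_time_s = out$postpone_time_s_scr,
    screening_postpone_k = dplyr::coalesce(out$postpone_k_scr, 0L),
    support_complete_time_s = out$complete_time_s_sup,
    support_complete_k = dplyr::coalesce(out$complete_k_sup, 0L),
    support_postpone_time_s = out$postpone_time_s_sup,
    support_postpone_k = dplyr::coalesce(out$postpone_k_sup, 0L)
  ) |>
    dplyr::arrange(.data$encounter_id)
}
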