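# Completion, burden and stratification metrics computed from encounter
# outcomes and alert episodes.

COMPLETION_DEFINITIONS <- c("ack", "documented", "discussion", "referral",
                            "no_postpone", "ready_to_quit")

definition_columns <- function(definition) {
  switch(definition,
    ack           = list(flag = "screening_ack_completed", denom = "screening_fired"),
    documented    = list(flag = "screening_documented",    denom = "screening_fired"),
    discussion    = list(flag = "support_discussed",       denom = "support_fired"),
    referral      = list(flag = "support_referral_ordered", denom = "support_fired"),
    no_postpone   = list(flag = "support_no_postpone",     denom = "support_fired"),
    ready_to_quit = list(flag = "support_ready_to_quit",   denom = "support_fired"),
    abort_config(paste0("unknown completion definition: ", definition))
  )
}

filter_outcomes <- function(outcomes, clinic = NULL, window = NULL,
                            relevance = NULL, sex = NULL, race = NULL,
                            in_window_only = TRUE) {
  desc <- character(0)
  if (in_window_only) {
    outcomes <- outcomes[!is.na(outcomes$window_index), ]
    desc <- c(desc, "within 12 months of go-live")
  }
  for (key in c("clinic", "window", "relevance", "sex", "race")) {
    val <- switch(key, clinic = clinic, window = window,
                  relevance = relevance, sex = sex, race = race)
    if (!is.null(val)) {
      col <- switch(key, clinic = "clinic_id", window = "window_index",
                    key)
      outcomes <- outcomes[outcomes[[col]] %in% val, ]
      desc <- c(desc, paste0(col, " in {", paste(val, collapse = ","), "}"))
    }
  }
  attr(outcomes, "filter_desc") <- if (length(desc) == 0) "all encounters"
                                   else paste(desc, collapse = "; ")
  outcomes
}

#' Encounter-level alert completion rate
#'
#' The number of encounters in which the alert-prompted action was completed
#' divided by the number of encounters in which the alert fired, under one of
#' six completion definitions: `ack` (staff acknowledged completion of
#' screening), `documented` (screening results documented in the flowsheet),
#' `discussion` (provider discussed cessation and assessed readiness to
#' quit), `referral` (referral to the cessation clinic ordered through the
#' alert), `no_postpone` (provider responded without ever postponing) and
#' `ready_to_quit` (patient identified as ready to quit). Screening
#' definitions use encounters where the screening alert fired as the
#' denominator; support definitions use encounters where the support alert
#' fired.
#'
#' @param outcomes Encounter outcomes from [rollup_encounters()].
#' @param definition One of the definitions above.
#' @param clinic,window,relevance,sex,race Optional filters restricting the
#'   denominator to the matching encounters.
#' @param in_window_only Restrict to encounters within the monitored
#'   12 months (default TRUE).
#' @return One-row tibble: `definition`, `numerator`, `denominator`, `rate`,
#'   `filter`.
#' @export
completion_rate <- function(outcomes, definition = "ack", clinic = NULL,
                            window = NULL, relevance = NULL, sex = NULL,
                            race = NULL, in_window_only = TRUE) {
  definition <- match.arg(definition, COMPLETION_DEFINITIONS)
  cols <- definition_columns(definition)
  sub <- filter_outcomes(outcomes, clinic, window, relevance, sex, race,
                         in_window_only)
  denom <- sum(sub[[cols$denom]])
  if (denom == 0) {
    rlang::abort(paste0("completion rate undefined: no encounters where the ",
                        "alert fired under filter [",
                        attr(sub, "filter_desc"), "]"),
                 class = "alertmetrics_undefined_rate")
  }
  num <- sum(sub[[cols$flag]] & sub[[cols$denom]])
  tibble::tibble(definition = definition, numerator = num,
                 denominator = denom, rate = num / denom,
                 filter = attr(sub, "filter_desc"))
}

#' Completion-rate trend over 3-month windows
#'
#' One completion rate per clinic and 3-month window (windows indexed from
#' each clinic's own go-live date), plus pooled `ALL` rows per window.
#' Clinic-window cells in which the alert never fired are omitted.
#'
#' @inheritParams completion_rate
#' @param n_windows Number of 3-month windows (default 4).
#' @return Tibble with columns `clinic_id` (or `"ALL"`), `window_index`,
#'   `definition`, `numerator`, `denominator`, `rate`.
#' @export
completion_trend <- function(outcomes, definition = "ack", n_windows = 4) {
  definition <- match.arg(definition, COMPLETION_DEFINITIONS)
  cols <- definition_columns(definition)
  sub <- outcomes[!is.na(outcomes$window_index) &
                    outcomes$window_index < n_windows, ]
  cell <- function(df, clinic_label) {
    df |>
      dplyr::group_by(.data$window_index) |>
      dplyr::summarise(numerator = sum(.data[[cols$flag]] & .data[[cols$denom]]),
                       denominator = sum(.data[[cols$denom]]),
                       .groups = "drop") |>
      dplyr::filter(.data$denominator > 0) |>
      dplyr::mutate(clinic_id = clinic_label, definition = definition,
                    rate = .data$numerator / .data$denominator)
  }
  per_clinic <- split(sub, sub$clinic_id) |>
    purrr::imap(~ cell(.x, .y)) |>
    dplyr::bind_rows()
  pooled <- cell(sub, "ALL")
  dplyr::bind_rows(per_clinic, pooled) |>
    dplyr::select("clinic_id", "window_index", "definition", "numerator",
                  "denominator", "rate") |>
    dplyr::arrange(.data$clinic_id != "ALL", .data$clinic_id,
                   .data$window_index)
}

#' Alert firing rate (firings per completion)
#'
#' The number of times the alert fired during the monitored period divided
#' by the number of times it was completed during that period — the average
#' number of firings needed per completion, a burden marker. Computed over
#' episodes (not encounters) because an encounter-level rate is undefined
#' for encounters that never complete the alert; when no episode in scope
#' completed, the rate is flagged undefined rather than thrown. By default
#' only interruptive episodes are counted, mirroring the burden focus on
#' interruptions; set `interruptive_only = FALSE` to include passive
#' (noninterruptive) firings.
#'
#' @param episodes Episode table from [build_episodes()].
#' @param kind `"screening"` or `"support"`.
#' @param clinic Optional clinic id(s) restricting scope.
#' @param window Optional window index(es) restricting the period.
#' @param interruptive_only Count interruptive episodes only (default TRUE).
#' @param in_window_only Restrict to episodes within the monitored 12 months.
#' @return One-row tibble: `alert_kind`, `scope`, `fired`, `completed`,
#'   `rate` (NA when undefined), `undefined`.
#' @export
firing_rate <- function(episodes, kind = "screening", clinic = NULL,
                        window = NULL, interruptive_only = TRUE,
                        in_window_only = TRUE) {
  kind <- match.arg(kind, ALERT_KINDS)
  sub <- episodes[episodes$alert_kind == kind, ]
  scope <- "overall"
  if (in_window_only) sub <- sub[!is.na(sub$window_index), ]
  if (interruptive_only) sub <- sub[sub$modality == "interruptive", ]
  if (!is.null(clinic)) {
    sub <- sub[sub$clinic_id %in% clinic, ]
    scope <- paste(clinic, collapse = ",")
  }
  if (!is.null(window)) {
    sub <- sub[sub$window_index %in% window, ]
    scope <- paste0(scope, " window ", paste(window, collapse = ","))
  }
  fired <- sum(sub$n_firings)
  completed <- sum(sub$completed)
  tibble::tibble(alert_kind = kind, scope = scope, fired = fired,
                 completed = completed,
                 rate = if (completed > 0) fired / completed else NA_real_,
                 undefined = completed == 0)
}

#' Per-encounter alert handling time
#'
#' Average time providers spent completing an alert per encounter, over
#' encounters in which the alert was completed, and average time spent
#' postponing per encounter, over encounters in which the alert was
#' postponed at least once. The two encounter sets overlap: an encounter
#' postponed twice and then completed contributes to both averages. Within
#' an encounter, completing time sums the durations of instances with a
#' responding (non-defer) action and postponing time sums defer-instance
#' durations. `aggregate = "instance"` switches to per-instance averaging
#' (total seconds over total instances) instead of per-encounter sums.
#'
#' @param outcomes Encounter outcomes from [rollup_encounters()].
#' @param kind `"screening"` or `"support"`.
#' @param aggregate `"encounter"` (default) or `"instance"`.
#' @param in_window_only Restrict to encounters within the monitored 12
#'   months.
#' @return One-row tibble: `alert_kind`, `mean_complete_s`,
#'   `n_complete_encounters`, `mean_postpone_s`, `n_postpone_encounters`.
#'   Means are `NA` when their encounter set is empty.
#' @export
handling_time <- function(outcomes, kind = "screening",
                          aggregate = c("encounter", "instance"),
                          in_window_only = TRUE) {
  kind <- match.arg(kind, ALERT_KINDS)
  aggregate <- match.arg(aggregate)
  sub <- if (in_window_only) outcomes[!is.na(outcomes$window_index), ]
         else outcomes
  flag <- if (kind == "screening") sub$screening_ack_completed
          else sub$support_discussed
  postponed <- if (kind == "screening") sub$screening_deferred_any
               else sub$support_deferred_any
  ct <- sub[[paste0(kind, "_complete_time_s")]]
  ck <- sub[[paste0(kind, "_complete_k")]]
  pt <- sub[[paste0(kind, "_postpone_time_s")]]
  pk <- sub[[paste0(kind, "_postpone_k")]]

  comp <- flag & !is.na(ct)
  post <- postponed & !is.na(pt)
  mean_by <- function(times, counts, sel) {
    if (sum(sel) == 0) return(NA_real_)
    if (aggregate == "encounter") mean(times[sel])
    else sum(times[sel]) / sum(counts[sel])
  }
  tibble::tibble(
    alert_kind = kind,
    mean_complete_s = mean_by(ct, ck, comp),
    n_complete_encounters = sum(comp),
    mean_postpone_s = mean_by(pt, pk, post),
    n_postpone_encounters = sum(post)
  )
}

#' Completion rate stratified by demographics, relevance or clinic
#'
#' One completion rate per observed combination of the stratification keys.
#' Strata partition the encounters, so stratum numerators and denominators
#' sum to the unstratified totals.
#'
#' @inheritParams completion_rate
#' @param keys Subset of `c("sex", "race", "relevance", "clinic")`.
#' @param drop_empty Drop strata in which the alert never fired (default
#'   TRUE; their rate is undefined).
#' @return Tibble with one row per stratum: key columns plus `definition`,
#'   `numerator`, `denominator`, `rate`.
#' @export
stratify_completion <- function(outcomes, definition = "ack",
                                keys = "relevance", in_window_only = TRUE,
                                drop_empty = TRUE) {
  definition <- match.arg(definition, COMPLETION_DEFINITIONS)
  keys <- match.arg(keys, c("sex", "race", "relevance", "clinic"),
                    several.ok = TRUE)
  cols <- definition_columns(definition)
  key_cols <- ifelse(keys == "clinic", "clinic_id", keys)
  sub <- if (in_window_only) outcomes[!is.na(outcomes$window_index), ]
         else outcomes
  res <- sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(
      definition = definition,
      numerator = sum(.data[[cols$flag]] & .data[[cols$denom]]),
      denominator = sum(.data[[cols$denom]]),
      .groups = "drop") |>
    dplyr::mutate(rate = ifelse(.data$denominator > 0,
                                .data$numerator / .data$denominator,
                                NA_real_))
  if (drop_empty) res <- res[res$denominator > 0, ]
  res
}

#' Two-proportion comparison (Pearson chi-square)
#'
#' Compares completion proportions between two groups of encounters with the
#' Pearson chi-square test on the 2x2 table, 1 degree of freedom, no
#' continuity correction, two-sided. Degenerate tables (pooled successes or
#' failures all zero) return statistic 0 and p = 1.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  if ((x1 + x2) == 0 || (x1 + x2) == (n1 + n2)) {
    return(tibble::tibble(statistic = 0, df = 1L, p_value = 1))
  }
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  # the small-expected-count warning is informational here: the statistic is
  # the Pearson chi-square by definition, whatever the cell sizes
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic), df = 1L,
                 p_value = unname(res$p.value))
}

#' Round a metric for reporting
#'
#' Reporting convention: completion rates to 2 decimals, firing rates to 1
#' decimal, handling times to integer seconds, percentages to 1 decimal.
#'
#' @param x Numeric value(s).
#' @param what One of `"rate"`, `"firing"`, `"seconds"`, `"percent"`.
#' @return Rounded numeric.
#' @export
round_metric <- function(x, what = c("rate", "firing", "seconds", "percent")) {
  what <- match.arg(what)
  switch(what,
    rate = round(x, 2),
    firing = round(x, 1),
    seconds = round(x, 0),
    percent = round(x, 1))
}
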