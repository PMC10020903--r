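# Pipeline orchestration: run every metric on a dataset, emit tidy CSV and a
# nested JSON summary, and flag per-clinic deviations.

#' Compute the full metric set for a dataset
#'
#' Runs episode reconstruction and the encounter roll-up, then computes the
#' completion rates under every definition supported by the data, the
#' 3-month completion trend, overall and per-clinic firing rates, handling
#' times, relevance/sex/race stratifications and the relevance
#' two-proportion test.
#'
#' @param d A valid [alert_dataset()].
#' @param relevance_map Named character vector (encounter type ->
#'   relevance); defaults to the packaged example map.
#' @param required_questions Screener questions required for documentation.
#' @param n_windows Number of 3-month windows.
#' @return List with `episodes`, `outcomes`, `completion`, `trend`,
#'   `firing`, `handling`, `strata`, `relevance_test` and a nested `summary`
#'   list mirroring the headline numbers.
#' @export
compute_metrics <- function(d, relevance_map = example_relevance_map(),
                            required_questions = c("Q1", "Q2", "Q3"),
                            n_windows = 4) {
  episodes <- build_episodes(d, n_windows = n_windows)
  outcomes <- rollup_encounters(episodes, d, relevance_map,
                                required_questions)
  inwin <- outcomes[!is.na(outcomes$window_index), ]
  has_screening <- sum(inwin$screening_fired) > 0
  has_support <- sum(inwin$support_fired) > 0

  defs <- c(if (has_screening) c("ack", "documented"),
            if (has_support) c("discussion", "referral", "no_postpone",
                               "ready_to_quit"))
  completion <- dplyr::bind_rows(
    lapply(defs, function(def) completion_rate(outcomes, def)))

  trend <- if (has_screening) {
    dplyr::bind_rows(completion_trend(outcomes, "ack", n_windows),
                     completion_trend(outcomes, "documented", n_windows))
  } else NULL

  clinic_ids <- sort(unique(d$clinics$clinic_id))
  firing <- list()
  for (kind in ALERT_KINDS) {
    eps <- episodes[episodes$alert_kind == kind, ]
    if (nrow(eps) == 0) next
    firing[[length(firing) + 1]] <-
      dplyr::mutate(firing_rate(episodes, kind), clinic_id = "ALL")
    for (cid in intersect(clinic_ids, unique(eps$clinic_id))) {
      firing[[length(firing) + 1]] <-
        dplyr::mutate(firing_rate(episodes, kind, clinic = cid),
                      clinic_id = cid)
    }
  }
  firing <- dplyr::bind_rows(firing)

  handling <- dplyr::bind_rows(
    if (has_screening) handling_time(outcomes, "screening"),
    if (has_support) handling_time(outcomes, "support"))

  strata <- dplyr::bind_rows(
    if (has_screening) dplyr::bind_rows(
      dplyr::mutate(stratify_completion(outcomes, "ack", "relevance"),
                    stratum = "relevance", value = .data$relevance),
      dplyr::mutate(stratify_completion(outcomes, "ack", "sex"),
                    stratum = "sex", value = .data$sex),
      dplyr::mutate(stratify_completion(outcomes, "ack", "race"),
                    stratum = "race", value = .data$race)),
    if (has_support) dplyr::bind_rows(
      dplyr::mutate(stratify_completion(outcomes, "discussion", "sex"),
                    stratum = "sex", value = .data$sex),
      dplyr::mutate(stratify_completion(outcomes, "discussion", "race"),
                    stratum = "race", value = .data$race))
  )
  if (nrow(strata) > 0) {
    strata <- strata[, c("stratum", "value", "definition", "numerator",
                         "denominator", "rate")]
  }

  relevance_test <- NULL
  if (has_screening) {
    rel <- stratify_completion(outcomes, "ack", "relevance")
    if (nrow(rel) == 2) {
      r1 <- rel[rel$relevance == "relevant", ]
      r2 <- rel[rel$relevance == "less_relevant", ]
      relevance_test <- two_proportion_test(r1$numerator, r1$denominator,
                                            r2$numerator, r2$denominator)
    }
  }

  summary <- build_summary(completion, firing, handling, strata,
                           relevance_test)
  list(episodes = episodes, outcomes = outcomes, completion = completion,
       trend = trend, firing = firing, handling = handling, strata = strata,
       relevance_test = relevance_test, summary = summary)
}

build_summary <- function(completion, firing, handling, strata,
                          relevance_test) {
  comp <- lapply(seq_len(nrow(completion)), function(i) {
    list(numerator = completion$numerator[i],
         denominator = completion$denominator[i],
         rate = completion$rate[i])
  })
  names(comp) <- completion$definition
  fir <- lapply(seq_len(nrow(firing)), function(i) {
    list(alert_kind = firing$alert_kind[i], clinic = firing$clinic_id[i],
         fired = firing$fired[i], completed = firing$completed[i],
         rate = firing$rate[i], undefined = firing$undefined[i])
  })
  han <- lapply(seq_len(nrow(handling)), function(i) {
    list(alert_kind = handling$alert_kind[i],
         mean_complete_s = handling$mean_complete_s[i],
         n_complete_encounters = handling$n_complete_encounters[i],
         mean_postpone_s = handling$mean_postpone_s[i],
         n_postpone_encounters = handling$n_postpone_encounters[i])
  })
  out <- list(completion = comp, firing_rate = fir, handling_time = han)
  if (!is.null(relevance_test)) {
    out$relevance_test <- list(statistic = relevance_test$statistic,
                               df = relevance_test$df,
                               p_value = relevance_test$p_value)
  }
  out
}

#' Write metric outputs to a directory
#'
#' Emits one tidy CSV per metric family (`completion.csv`, `trend.csv`,
#' `firing_rate.csv`, `handling_time.csv`, `strata.csv`,
#' `relevance_test.csv`), the encounter outcomes (`outcomes.csv`) and a
#' nested `summary.json`. All tables carry numerator/denominator provenance
#' columns.
#'
#' @param results Output of [compute_metrics()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_metrics <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      readr::write_csv(df, file.path(out_dir, name), na = "")
    }
  }
  wr(results$completion, "completion.csv")
  wr(results$trend, "trend.csv")
  wr(results$firing, "firing_rate.csv")
  wr(results$handling, "handling_time.csv")
  wr(results$strata, "strata.csv")
  wr(results$relevance_test, "relevance_test.csv")
  wr(results$outcomes, "outcomes.csv")
  jsonlite::write_json(results$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' Flag clinics deviating from the pooled completion rate
#'
#' Compares each clinic's windowed completion rate with the pooled (ALL)
#' rate of the same window and flags absolute deviations above the
#' threshold — a simple monitoring signal for clinic-level adoption
#' problems.
#'
#' @param trend Trend table from [completion_trend()] (or the `trend`
#'   element of [compute_metrics()] output).
#' @param threshold Absolute rate deviation that triggers a flag
#'   (default 0.15).
#' @param definition Completion definition to inspect (default `"ack"`).
#' @return Tibble: `clinic_id`, `window_index`, `rate`, `pooled_rate`,
#'   `deviation`, `flagged`.
#' @export
report_deviations <- function(trend, threshold = 0.15, definition = "ack") {
  trend <- trend[trend$definition == definition, ]
  pooled <- trend[trend$clinic_id == "ALL",
                  c("window_index", "rate")]
  names(pooled)[2] <- "pooled_rate"
  trend[trend$clinic_id != "ALL", ] |>
    dplyr::inner_join(pooled, by = "window_index") |>
    dplyr::mutate(deviation = .data$rate - .data$pooled_rate,
                  flagged = abs(.data$deviation) > threshold) |>
    dplyr::select("clinic_id", "window_index", "rate", "pooled_rate",
                  "deviation", "flagged") |>
    dplyr::arrange(.data$clinic_id, .data$window_index)
}
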