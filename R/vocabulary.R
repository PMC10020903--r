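# Controlled vocabularies for the event-log model.

# enum levels used throughout; kept as plain character vectors so tables stay
# readr/jsonlite friendly
SEX_LEVELS <- c("female", "male", "unknown")
RACE_LEVELS <- c("african_american", "white", "other", "unknown")
SMOKING_LEVELS <- c("current", "former", "never", "unknown")
ALERT_KINDS <- c("screening", "support")
TRIGGER_LEVELS <- c("chart_open", "chart_reopen", "timer_refire",
                    "noninterruptive_display")
SUBSEQUENT_ACTIONS <- c("acknowledge_override_warning", "none")
RELEVANCE_LEVELS <- c("relevant", "less_relevant")

#' Canonical provider actions on an alert
#'
#' The event log records the label of the button a provider pressed as a raw
#' `override_reason` string. Analysis works on a closed set of canonical
#' actions; the mapping from raw button labels to canonical actions is the
#' *action vocabulary* (see [read_vocabulary()]).
#'
#' @return Character vector of the six canonical actions:
#'   `ack_complete_screening` (staff acknowledged screening completion),
#'   `defer` (alert postponed), `not_appropriate` (patient deemed
#'   inappropriate for screening), `discussed_ready`, `discussed_not_ready`
#'   (provider discussed cessation; patient readiness), `not_discussed`.
#'   An instance with no response at all is assigned `no_response` by the
#'   episode builder; it is not part of the vocabulary.
#' @export
canonical_actions <- function() {
  c("ack_complete_screening", "defer", "not_appropriate",
    "discussed_ready", "discussed_not_ready", "not_discussed")
}

# canonical actions that constitute a response other than postponing
responding_actions <- function() setdiff(canonical_actions(), "defer")

# actions that complete an alert, by alert kind; screening completion is the
# staff acknowledgment, support completion is a documented discussion
completing_actions <- function(kind) {
  switch(kind,
    screening = "ack_complete_screening",
    support   = c("discussed_ready", "discussed_not_ready"),
    stop("unknown alert kind: ", kind)
  )
}

#' Default action vocabulary
#'
#' Maps the Epic-style button labels used by the bundled fixtures and the
#' simulator to canonical actions. Local deployments use different labels;
#' supply a custom mapping through `vocabulary.yaml` (see
#' [read_vocabulary()]). Matching is exact after trimming surrounding
#' whitespace and is case-sensitive.
#'
#' @return Named character vector: names are raw `override_reason` tokens,
#'   values are canonical actions.
#' @export
default_vocabulary <- function() {
  c("Documented in Flowsheet"       = "ack_complete_screening",
    "Defer"                         = "defer",
    "Not appropriate"               = "not_appropriate",
    "Discussed - Ready to quit"     = "discussed_ready",
    "Discussed - Not ready to quit" = "discussed_not_ready",
    "Not discussed"                 = "not_discussed")
}

#' Read an action vocabulary from YAML
#'
#' The file is a flat YAML mapping from raw override-reason label to
#' canonical action, e.g. `"Documented in Flowsheet": ack_complete_screening`.
#'
#' @param path Path to a YAML file.
#' @return Named character vector (raw token -> canonical action).
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("vocabulary file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    abort_config(paste0("vocabulary file must be a YAML mapping: ", path))
  }
  vocab <- vapply(raw, as.character, character(1))
  bad <- setdiff(unname(vocab), canonical_actions())
  if (length(bad) > 0) {
    abort_config(paste0("vocabulary maps to unknown canonical action(s): ",
                        paste(bad, collapse = ", ")))
  }
  vocab
}

#' Read an encounter-type relevance map
#'
#' Encounter types are free-text labels; physicians classify each type as
#' `relevant` or `less_relevant` to routine tobacco screening. The map is a
#' flat YAML mapping (`office_visit: relevant`) or a two-column CSV with
#' headers `encounter_type,relevance`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.csv` file.
#' @return Named character vector (encounter type -> relevance level).
#' @export
read_relevance_map <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("relevance map not found: ", path))
  }
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    map <- vapply(raw, as.character, character(1))
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    if (!all(c("encounter_type", "relevance") %in% names(df))) {
      abort_config("relevance map CSV needs columns encounter_type, relevance")
    }
    map <- stats::setNames(df$relevance, df$encounter_type)
  }
  bad <- setdiff(unname(map), RELEVANCE_LEVELS)
  if (length(bad) > 0) {
    abort_config(paste0("relevance map contains unknown level(s): ",
                        paste(unique(bad), collapse = ", ")))
  }
  map
}

#' Example relevance map bundled with the package
#'
#' Classifies the encounter types used by the bundled fixtures and the
#' simulator: office visits, initial consultations and follow-ups are
#' relevant occasions for routine tobacco screening; lab and treatment
#' visits are less relevant. Institutional lists differ; this map is a
#' documented example, not a standard.
#'
#' @return Named character vector (encounter type -> relevance level).
#' @export
example_relevance_map <- function() {
  read_relevance_map(system.file("extdata", "relevance-map.yaml",
                                 package = "alertmetrics", mustWork = TRUE))
}

# condition helpers -----------------------------------------------------------

abort_config <- function(message) {
  rlang::abort(message, class = "alertmetrics_config_error")
}

abort_schema <- function(message) {
  rlang::abort(message, class = "alertmetrics_schema_error")
}

abort_validation <- function(message) {
  rlang::abort(message, class = "alertmetrics_validation_error")
}
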