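#' Event-level 24-hour recall representation
#'
#' A recall day is a set of eating events: a clock time (minute of day,
#' 0--1439) and an energy amount (kcal). Each event is modelled as a
#' 15-minute eating occasion, so a day can equivalently be viewed as a
#' 1440-minute energy series with `energy_kcal / 15` kcal deposited in each
#' of the 15 minutes from the event's start.
#'
#' Event tables are tibbles with columns `participant_id`, `time_min`
#' (integer minute of day) and `energy_kcal` (positive). `time_min` may also
#' be given as `"HH:MM"` clock strings; see [read_events()].
#'
#' @name recall-model
NULL

OCCASION_MIN <- 15L
DAY_MIN <- 1440L

check_events <- function(events, require_id = FALSE) {
  if (!is.data.frame(events)) {
    abort("`events` must be a data frame with columns time_min and energy_kcal.")
  }
  need <- c("time_min", "energy_kcal")
  if (require_id) need <- c("participant_id", need)
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols)) {
    abort(paste0("`events` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(events) == 0L) {
    abort("`events` is empty: a recall day must have non-zero energy intake.")
  }
  if (any(!is.finite(events$energy_kcal)) || any(events$energy_kcal <= 0)) {
    abort("all `energy_kcal` values must be finite and > 0.")
  }
  if (any(events$time_min < 0 | events$time_min >= DAY_MIN)) {
    abort("all `time_min` values must lie in [0, 1440).")
  }
  invisible(events)
}

#' Merge simultaneously reported intake into single eating events
#'
#' Dietary recalls report one row per food, so several rows can share one
#' clock time. The pattern analysis reasons about eating events, not foods:
#' rows with identical `time_min` (within a participant, when
#' `participant_id` is present) are merged by summing their energy. The
#' result is sorted by time with strictly increasing times per participant.
#' The operation is idempotent.
#'
#' @param events Tibble with columns `time_min`, `energy_kcal` and
#'   optionally `participant_id`.
#' @return Tibble of the same shape with merged, time-ordered events.
#' @examples
#' merge_simultaneous_events(
#'   tibble::tibble(time_min = c(480L, 480L), energy_kcal = c(150, 300))
#' )
#' @export
merge_simultaneous_events <- function(events) {
  check_events(events)
  keys <- intersect(c("participant_id", "time_min"), names(events))
  events |>
    dplyr::summarise(
      energy_kcal = sum(.data$energy_kcal),
      .by = dplyr::all_of(keys)
    ) |>
    dplyr::arrange(dplyr::pick(dplyr::all_of(keys))) |>
    tibble::as_tibble()
}

#' Expand one participant's events into a 1440-minute energy series
#'
#' Each eating event is treated as a 15-minute occasion: its energy divided
#' by 15 is deposited into each of the 15 minutes starting at `time_min`.
#' Overlapping occasions sum. Occasions starting after minute 1425 are
#' truncated at the end of the day (no wrap past midnight), so the series
#' sum can fall below total event energy only in that case.
#'
#' @param events Events for a single recall day (single participant).
#' @return Numeric vector of length 1440, kcal per minute.
#' @examples
#' s <- events_to_minute_series(
#'   tibble::tibble(time_min = 480L, energy_kcal = 600)
#' )
#' sum(s) # 600
#' @export
events_to_minute_series <- function(events) {
  check_events(events)
  if ("participant_id" %in% names(events) &&
      dplyr::n_distinct(events$participant_id) > 1L) {
    abort("`events` holds several participants; supply one recall day.")
  }
  series <- numeric(DAY_MIN)
  per_min <- events$energy_kcal / OCCASION_MIN
  for (i in seq_len(nrow(events))) {
    idx <- events$time_min[i] + seq_len(OCCASION_MIN) # 1-based minutes
    idx <- idx[idx <= DAY_MIN]
    series[idx] <- series[idx] + per_min[i]
  }
  series
}

#' Read an event table from CSV
#'
#' Tolerant reader for the event-table dialect written by
#' [write_cohort()]: columns `participant_id`, `time_min`, `energy_kcal`.
#' `time_min` may hold integer minutes of day or `"HH:MM"` clock strings
#' (midnight = 0).
#'
#' @param path Path to a CSV file.
#' @return Event tibble with integer `time_min`.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(time_min = readr::col_character()))
  if (!"time_min" %in% names(ev)) abort("`time_min` column is required.")
  if (all(grepl("^[0-9]+$", ev$time_min))) {
    ev$time_min <- as.integer(ev$time_min)
  } else {
    ev$time_min <- parse_clock_time(ev$time_min)
  }
  check_events(ev, require_id = TRUE)
  ev
}

parse_clock_time <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("unparseable clock time(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  h <- vapply(m, function(p) as.integer(p[2]), 1L)
  mi <- vapply(m, function(p) as.integer(p[3]), 1L)
  if (any(h >= 24L | mi >= 60L)) abort("clock times must be within 00:00-23:59.")
  h * 60L + mi
}
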