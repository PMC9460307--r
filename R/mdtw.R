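#' MDTW configuration
#'
#' The modified dynamic time warping (MDTW) distance aligns two
#' participants' eating-event sequences and sums, along the optimal
#' monotone alignment, the local cost
#' \deqn{(\Delta e)^2 + \beta (\Delta t)^2,}
#' where \eqn{\Delta e} is the energy difference and \eqn{\Delta t} the
#' clock-time difference of the matched events, on the model scale. The
#' weight \eqn{\beta} penalizes time mismatches relative to energy
#' mismatches, discouraging pathological matchings such as aligning morning
#' with late-night intake.
#'
#' Units: times are divided by `time_scale` (default 60, i.e. hours) and
#' energies by `energy_scale` (default 100, i.e. 100-kcal units) before the
#' cost is evaluated. With these scales typical squared energy and weighted
#' squared time differences are of comparable magnitude near the default
#' `beta = 40`, so the weight meaningfully trades the two terms.
#'
#' @param beta Nonnegative time-penalty weight (default 40).
#' @param time_scale Positive divisor converting minutes to model time
#'   units (default 60).
#' @param energy_scale Positive divisor converting kcal to model energy
#'   units (default 100).
#' @return An object of class `mdtw_config`.
#' @export
mdtw_config <- function(beta = 40, time_scale = 60, energy_scale = 100) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    abort("`beta` must be a single nonnegative number.")
  }
  if (time_scale <= 0 || energy_scale <= 0) {
    abort("`time_scale` and `energy_scale` must be positive.")
  }
  structure(
    list(beta = beta, time_scale = time_scale, energy_scale = energy_scale),
    class = "mdtw_config"
  )
}

#' Local matching cost between two eating events
#'
#' Returns \eqn{(\Delta e)^2 + \beta (\Delta t)^2} on the model scale.
#' Symmetric in its arguments and zero iff the events coincide in scaled
#' time and energy. Vectorized over events.
#'
#' @param time_a,energy_a,time_b,energy_b Event times (minutes of day) and
#'   energies (kcal).
#' @param config An [mdtw_config()].
#' @return Nonnegative numeric cost(s).
#' @export
mdtw_local_cost <- function(time_a, energy_a, time_b, energy_b,
                            config = mdtw_config()) {
  de <- (energy_a - energy_b) / config$energy_scale
  dt <- (time_a - time_b) / config$time_scale
  de^2 + config$beta * dt^2
}

#' MDTW distance between two eating-event sequences
#'
#' Minimum, over all monotone alignments in which every event of each
#' sequence is matched to at least one event of the other (classic DTW
#' step set: match, repeat-left, repeat-right; no window constraint, no
#' path-length normalization), of the summed local costs. Computed by
#' dynamic programming. Symmetric and nonnegative; zero iff the sequences
#' are identical in scaled time and energy. The triangle inequality is not
#' guaranteed (DTW-type measures are not metrics).
#'
#' @param events_a,events_b Event tibbles for two recall days (columns
#'   `time_min`, `energy_kcal`), nonempty.
#' @param config An [mdtw_config()].
#' @return Nonnegative scalar distance.
#' @examples
#' a <- tibble::tibble(time_min = c(480L, 780L), energy_kcal = c(400, 700))
#' b <- tibble::tibble(time_min = 760L, energy_kcal = 900)
#' mdtw_distance(a, b)
#' @export
mdtw_distance <- function(events_a, events_b, config = mdtw_config()) {
  check_events(events_a)
  check_events(events_b)
  events_a <- dplyr::arrange(events_a, .data$time_min)
  events_b <- dplyr::arrange(events_b, .data$time_min)
  mdtw_dist_cpp(
    events_a$time_min / config$time_scale,
    events_a$energy_kcal / config$energy_scale,
    events_b$time_min / config$time_scale,
    events_b$energy_kcal / config$energy_scale,
    config$beta
  )
}

#' Pairwise MDTW distance matrix over a cohort
#'
#' Computes the symmetric matrix of MDTW distances between every pair of
#' participants' recall days. Simultaneous events are merged first (see
#' [merge_simultaneous_events()]).
#'
#' @param events Cohort event tibble with `participant_id`, `time_min`,
#'   `energy_kcal`; at least two participants.
#' @param config An [mdtw_config()].
#' @return Symmetric numeric matrix with zero diagonal; participant ids as
#'   dimnames.
#' @export
mdtw_pairwise <- function(events, config = mdtw_config()) {
  check_events(events, require_id = TRUE)
  events <- merge_simultaneous_events(events)
  ids <- unique(events$participant_id)
  if (length(ids) < 2L) abort("need at least 2 participants.")
  events <- dplyr::arrange(events, match(.data$participant_id, ids),
                           .data$time_min)
  len <- as.integer(table(factor(events$participant_id, levels = ids)))
  start <- c(0L, cumsum(len)[-length(len)])
  D <- mdtw_pairwise_cpp(
    events$time_min / config$time_scale,
    events$energy_kcal / config$energy_scale,
    start, len, config$beta
  )
  dimnames(D) <- list(as.character(ids), as.character(ids))
  D
}

#' Write / read a distance matrix as CSV
#'
#' The matrix is stored square with participant ids as the header row and
#' first column.
#'
#' @param D Symmetric distance matrix with id dimnames.
#' @param path CSV path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the matrix.
#' @export
write_distance_matrix <- function(D, path) {
  df <- tibble::as_tibble(D, rownames = "participant_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- as.character(df[[1]])
  storage.mode(D) <- "double"
  D
}
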