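#' Time-by-energy density grid per cluster
#'
#' The heat-map representation of a temporal dietary pattern: for each
#' cluster, the percentage of its members reporting at least one eating
#' event in each (time-of-day, energy) cell. A participant contributes at
#' most once per cell regardless of how many events fall in it, so values
#' are percentages of participants in \[0, 100\]. Events are binned by
#' their (time, energy) occasion pairs, not by the expanded 1440-minute
#' series.
#'
#' @param events Cohort event tibble (`participant_id`, `time_min`,
#'   `energy_kcal`).
#' @param labels Tibble mapping `participant_id` to `cluster` (e.g. from
#'   [tidy.tdp_clusters()] or [classify_cohort()] renamed), or a vector of
#'   labels ordered like `unique(events$participant_id)`.
#' @param time_bin_min Time bin width in minutes (default 60, hourly).
#' @param energy_bin_kcal Energy bin width in kcal (default 100).
#' @param energy_max_kcal Upper energy axis limit (default 4000); events
#'   above it are placed in the top bin.
#' @return Long tibble of class `tdp_density`: `cluster`, `time_bin`
#'   (left edge, minutes), `energy_bin` (left edge, kcal), `pct`. Clusters
#'   with no members yield `NA` percentages. Grid geometry is carried in
#'   attributes `time_bin_min`, `energy_bin_kcal`, `energy_max_kcal`.
#' @export
compute_density <- function(events, labels, time_bin_min = 60,
                            energy_bin_kcal = 100, energy_max_kcal = 4000) {
  check_events(events, require_id = TRUE)
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(participant_id = unique(events$participant_id),
                             cluster = labels)
  }
  if (!all(c("participant_id", "cluster") %in% names(labels))) {
    abort("`labels` must have columns participant_id and cluster.")
  }
  if (!all(events$participant_id %in% labels$participant_id)) {
    abort("`labels` must cover every participant in `events`.")
  }
  sizes <- dplyr::count(labels, .data$cluster, name = "cluster_n")
  n_time <- ceiling(DAY_MIN / time_bin_min)
  n_energy <- ceiling(energy_max_kcal / energy_bin_kcal)
  cells <- events |>
    dplyr::left_join(labels, by = "participant_id") |>
    dplyr::mutate(
      time_bin = pmin(.data$time_min %/% time_bin_min, n_time - 1L) * time_bin_min,
      energy_bin = pmin(floor(.data$energy_kcal / energy_bin_kcal),
                        n_energy - 1L) * energy_bin_kcal
    ) |>
    dplyr::distinct(.data$participant_id, .data$cluster, .data$time_bin,
                    .data$energy_bin) |>
    dplyr::count(.data$cluster, .data$time_bin, .data$energy_bin)
  grid <- tidyr::expand_grid(
    cluster = sort(unique(labels$cluster)),
    time_bin = seq(0, by = time_bin_min, length.out = n_time),
    energy_bin = seq(0, by = energy_bin_kcal, length.out = n_energy)
  ) |>
    dplyr::left_join(cells, by = c("cluster", "time_bin", "energy_bin")) |>
    dplyr::left_join(sizes, by = "cluster") |>
    dplyr::mutate(
      pct = dplyr::if_else(.data$cluster_n > 0,
                           100 * dplyr::coalesce(.data$n, 0L) / .data$cluster_n,
                           NA_real_)
    ) |>
    dplyr::select("cluster", "time_bin", "energy_bin", "pct")
  structure(grid, class = c("tdp_density", class(grid)),
            time_bin_min = time_bin_min, energy_bin_kcal = energy_bin_kcal,
            energy_max_kcal = energy_max_kcal)
}

#' Heat-map of a time-by-energy density grid
#'
#' One panel per cluster; the x axis runs 00:00--24:00, the y axis
#' 0--`energy_max_kcal` kcal, and shading is monotone in the percentage of
#' cluster members reporting intake in the cell (darker = greater), with
#' the scale upper limit at the grid maximum.
#'
#' @param object A `tdp_density` grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tdp_density <- function(object, ...) {
  grid_max <- max(object$pct, na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time_bin + attr(object, "time_bin_min") / 2,
    y = .data$energy_bin + attr(object, "energy_bin_kcal") / 2,
    fill = .data$pct
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ cluster, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient(
      name = "% of cluster", low = "white", high = "grey10",
      limits = c(0, grid_max)
    ) +
    ggplot2::scale_x_continuous(
      breaks = seq(0, 1440, 360),
      labels = sprintf("%02d:00", seq(0, 24, 6)),
      expand = c(0, 0)
    ) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "Time of day", y = "Energy (kcal)") +
    ggplot2::theme_minimal()
}

#' Render a density grid to an image file
#'
#' @param grid A `tdp_density` grid.
#' @param out_path Output path (extension chooses the device, e.g.
#'   `.png`).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `out_path` invisibly; the plot's fill-scale upper limit equals
#'   the grid maximum.
#' @export
render_heatmap <- function(grid, out_path, width = 8, height = 6, dpi = 150) {
  p <- autoplot(grid)
  ggplot2::ggsave(out_path, plot = p, width = width, height = height,
                  dpi = dpi)
  invisible(out_path)
}
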