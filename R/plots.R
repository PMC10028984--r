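#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a circuit trajectory
#'
#' Four stacked panels: ERK activity with its cumulative dose, the
#' transcription indicators, and the two protein levels, over developmental
#' time. Mitosis gaps are visible as indicator dropouts.
#'
#' @param traj a `circuit_trajectory` from [simulate_embryo()].
#' @return a ggplot object.
#' @export
plot_trajectory <- function(traj) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(traj),
    cols = c("E", "W", "x_tll", "x_hkb", "x_byn", "P_T", "P_H"),
    names_to = "series", values_to = "value")
  long$panel <- dplyr::case_when(
    long$series %in% c("E") ~ "ERK activity",
    long$series %in% c("W") ~ "cumulative dose",
    long$series %in% c("x_tll", "x_hkb", "x_byn") ~ "transcription",
    TRUE ~ "protein")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min since NC10 start)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circuit_trajectory <- function(object, ...) plot_trajectory(object)

#' Plot proportion-bursting curves
#'
#' @param prop tibble from [proportion_bursting()]; either per-cycle or
#'   per-timepoint.
#' @return a ggplot object.
#' @export
plot_proportion <- function(prop) {
  if ("t" %in% names(prop)) {
    ggplot2::ggplot(prop, ggplot2::aes(x = .data$t, y = .data$proportion)) +
      ggplot2::geom_line() +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "time (min)", y = "proportion of nuclei bursting") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(prop, ggplot2::aes(x = factor(.data$cycle),
                                       y = .data$proportion)) +
      ggplot2::geom_col() +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "nuclear cycle", y = "proportion of nuclei bursting") +
      ggplot2::theme_minimal()
  }
}

#' Kymograph of a stripe simulation
#'
#' Position-time raster of one field of the per-position circuit dynamics,
#' with the illumination boundary marked.
#'
#' @param stripe a `stripe_sim`.
#' @param what `"x_byn"`, `"x_tll"`, `"x_hkb"`, `"E"`, `"P_T"` or `"P_H"`.
#' @return a ggplot object.
#' @export
plot_kymograph <- function(stripe, what = "x_byn") {
  m <- stripe$circuit[[what]]
  df <- expand.grid(t = stripe$circuit$t, x = stripe$circuit$x)
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$t,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = stripe$boundary, linetype = 2,
                        colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (um from boundary)", y = "time (min)",
                  fill = what) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stripe_sim <- function(object, ...) plot_kymograph(object, ...)

#' Plot the repressor delay curve
#'
#' Onset times of both branches against ERK amplitude; the activator onset is
#' flat while the repressor onset scales like 1/amplitude, the signature of a
#' cumulative-dose threshold.
#'
#' @param curve tibble from [hkb_delay_curve()].
#' @return a ggplot object.
#' @export
plot_delay_curve <- function(curve) {
  long <- tidyr::pivot_longer(curve, cols = c("tll_onset", "hkb_onset"),
                              names_to = "gene", values_to = "onset")
  long <- long[is.finite(long$onset), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$amplitude, y = .data$onset,
                                     colour = .data$gene)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "ERK amplitude", y = "onset time (min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Burst-mask visualisation of one movie frame
#'
#' Renders the MCP channel with the nuclei currently in a bursting state
#' outlined, the mask-colouring convention of live-imaging figures.
#'
#' @param movie a `synthetic_movie`.
#' @param frame frame index.
#' @param table optional `burst_table` (defaults to ground truth bursts).
#' @return a ggplot object.
#' @export
plot_burst_frame <- function(movie, frame, table = NULL) {
  img <- movie$frames[, , 1, frame]
  px <- movie$pixel_size
  df <- expand.grid(
    y = seq(movie$window_y[1] + px / 2, movie$window_y[2] - px / 2, by = px),
    x = seq(movie$window_x[1] + px / 2, movie$window_x[2] - px / 2, by = px))
  df$value <- as.vector(img)
  tt <- movie$frame_times[frame]
  if (is.null(table)) {
    bb <- movie$truth_bursts
    bursting <- bb[bb$t_on <= tt & bb$t_off >= tt, , drop = FALSE]
  } else {
    bursting <- table[in_bursting_state(table, tt), , drop = FALSE]
  }
  sch <- movie$metadata$schedule
  cyc <- cycle_at(tt, sch)
  nuc <- movie$truth_nuclei[movie$truth_nuclei$cycle %in% cyc &
                              movie$truth_nuclei$nucleus_id %in%
                                bursting$nucleus_id, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("t = %.1f min", tt), fill = "a.u.") +
    ggplot2::theme_void()
  if (nrow(nuc) > 0) {
    circ <- purrr::map_dfr(seq_len(nrow(nuc)), function(i) {
      a <- seq(0, 2 * pi, length.out = 60)
      tibble::tibble(id = nuc$nucleus_id[i],
                     x = nuc$x[i] + nuc$r[i] * cos(a),
                     y = nuc$y[i] + nuc$r[i] * sin(a))
    })
    p <- p + ggplot2::geom_path(
      data = circ, ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
      colour = "orange", inherit.aes = FALSE)
  }
  p
}
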