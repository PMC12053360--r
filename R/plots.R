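# ggplot2 figures mirroring the standard presentation of rotating-cell
# tracking data: landmark trajectory scatter, angle time courses, cumulative
# angle curves and frequency box plots.

#' Plot tip and base trajectories of a track
#'
#' @param track a [cell_track()].
#' @param every plot every n-th frame to keep the figure light (default 5).
#' @return a ggplot object.
#' @export
plot_trajectory <- function(track, every = 5) {
  fr <- track$frames[seq(1, nrow(track$frames), by = every), ]
  df <- rbind(
    data.frame(x = fr$tip_x, y = fr$tip_y, landmark = "tip"),
    data.frame(x = fr$base_x, y = fr$base_y, landmark = "base")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$landmark)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = track$cell_id, x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot body and flagellar angle time courses
#'
#' Two stacked panels: wrapped body angle on top, flagellar angle below.
#'
#' @param body,flagellar [angle_series()] objects from the same track.
#' @param t_max optional upper time limit in seconds for readability.
#' @return a ggplot object.
#' @export
plot_angle_timecourse <- function(body, flagellar, t_max = NULL) {
  df <- rbind(
    cbind(as.data.frame(body), signal = "body angle"),
    cbind(as.data.frame(flagellar), signal = "flagellar angle")
  )
  df <- df[df$valid, ]
  if (!is.null(t_max)) df <- df[df$t_s <= t_max, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$theta_rad)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (rad)") +
    ggplot2::theme_minimal()
}

#' Plot cumulative angle curves for many cells
#'
#' Positive slope corresponds to counterclockwise rotation.
#'
#' @param series_list named list of cumulative [angle_series()] (names =
#'   cell ids).
#' @param condition_map optional named character vector cell id -> condition
#'   for colouring.
#' @return a ggplot object.
#' @export
plot_cumulative_angles <- function(series_list, condition_map = NULL) {
  df <- do.call(rbind, lapply(names(series_list), function(id) {
    d <- as.data.frame(series_list[[id]])
    d <- d[d$valid, ]
    d$cell_id <- id
    d$condition <- if (!is.null(condition_map)) condition_map[[id]] else "all"
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$theta_rad,
                                   group = .data$cell_id,
                                   colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "cumulative angle (rad)") +
    ggplot2::theme_minimal()
}

#' Box plot of frequencies by condition
#'
#' Boxes use the 1.5 IQR whisker convention of [box_stats()]; individual
#' cells are overlaid as points.
#'
#' @param per_cell per-cell record data frame.
#' @param column `"beat_hz"` or `"rotfreq_hz"`.
#' @param ylab axis label.
#' @return a ggplot object.
#' @export
plot_freq_box <- function(per_cell, column = c("beat_hz", "rotfreq_hz"),
                          ylab = NULL) {
  column <- match.arg(column)
  df <- per_cell[!is.na(per_cell[[column]]), ]
  if (is.null(ylab)) {
    ylab <- if (column == "beat_hz") "flagellar beat frequency (Hz)"
            else "rotational frequency (Hz)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data[[column]])) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
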