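#' Plot a trajectory coloured by speed class
#'
#' Path segments drawn in the tracker's convention: red for high speed,
#' green for low, black for inactive, over the well outline and divider.
#'
#' @param traj a [trajectory()].
#' @param well a [well_geometry()].
#' @param thresholds a [speed_thresholds()].
#' @return a ggplot object.
#' @export
plot_trajectory <- function(traj, well, thresholds = speed_thresholds()) {
  cls <- classify_speed(instantaneous_speeds(traj), thresholds)
  n <- nrow(traj)
  seg <- tibble::tibble(x = traj$x[-n], y = traj$y[-n],
                        xend = traj$x[-1], yend = traj$y[-1],
                        class = cls)
  ang <- seq(0, 2 * pi, length.out = 200)
  ring <- tibble::tibble(x = well$centre[1] + well$radius * cos(ang),
                         y = well$centre[2] + well$radius * sin(ang))
  tangent <- c(-well$divider_normal[2], well$divider_normal[1])
  div <- tibble::tibble(
    x = well$centre[1] + c(-1, 1) * well$radius * tangent[1],
    y = well$centre[2] + c(-1, 1) * well$radius * tangent[2])
  ggplot2::ggplot() +
    ggplot2::geom_path(data = ring, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey50") +
    ggplot2::geom_line(data = div, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey50", linetype = 2) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$class),
      linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(inactive = "black", low = "green3", high = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "speed class",
                  title = larva_id_of(traj)) +
    ggplot2::theme_minimal()
}

#' Plot a dF/F0 trace with detected transients
#'
#' @param dff dF/F0 series from [delta_f_over_f()].
#' @param dt sampling interval (s).
#' @param transients a [detect_transients()] result.
#' @return a ggplot object.
#' @export
plot_transients <- function(dff, dt, transients) {
  tr <- tibble::tibble(t = (seq_along(dff) - 1) * dt, dff = as.numeric(dff))
  pk <- tibble::tibble(t = transients$peak_times,
                       dff = transients$peak_amplitudes)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$dff)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = pk, colour = "red", shape = 25,
                        fill = "red", size = 2) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
}
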