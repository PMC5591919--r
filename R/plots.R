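#' Plot the displacement signal of selected markers
#'
#' @param sm Tibble from [smooth_and_differentiate()].
#' @param markers Marker ids to show (default: first three).
#' @return A ggplot object: raw displacement (points) with the smoothed
#'   signal overlaid.
#' @export
plot_displacement <- function(sm, markers = NULL) {
  markers <- markers %||% head(unique(sm$marker_id), 3)
  d <- dplyr::filter(sm, .data$marker_id %in% markers)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$d_px), size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$d_s), color = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$marker_id), ncol = 1) +
    ggplot2::labs(x = "time [s]", y = "displacement [px]") +
    ggplot2::theme_minimal()
}

#' Plot marker trajectories in the image plane
#'
#' @param ts Trajectory tibble.
#' @return A ggplot object with the y axis flipped to match image
#'   coordinates (y grows downward).
#' @export
plot_trajectories <- function(ts) {
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                   group = .data$marker_id)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [px]", y = "y [px]") +
    ggplot2::theme_minimal()
}

#' Plot the B_Z profiles of a field map
#'
#' Vertical-field profiles along the X and Y lines through the center of
#' the culture plane, with the central quasihomogeneity region shaded.
#'
#' @param map Tibble from [pair_field_map()].
#' @param region_halfwidth Shaded region half-width, m (default: central
#'   30% of the span).
#' @return A ggplot object.
#' @export
plot_field_profile <- function(map, region_halfwidth = NULL) {
  span <- max(map$coord_m) - min(map$coord_m)
  rh <- region_halfwidth %||% (0.3 * span / 2)
  ggplot2::ggplot(map, ggplot2::aes(x = .data$coord_m * 1e3, y = .data$Bz_mT)) +
    ggplot2::annotate("rect", xmin = -rh * 1e3, xmax = rh * 1e3,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "position [mm]", y = expression(B[Z] ~ "[mT]")) +
    ggplot2::theme_minimal()
}
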