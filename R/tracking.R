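#' Place the orthogonal marker grid on the first frame
#'
#' Markers sit at the nodes of a uniform lattice spanning
#' `[margin, width - margin] x [margin, height - margin]`, mirroring the
#' systematic 30-spot grid used to register syncytium movement.
#'
#' @param width,height Frame size in px.
#' @param rows Number of grid rows (y direction), default 5.
#' @param cols Number of grid columns (x direction), default 6.
#' @param margin Clearance from the frame border, px.
#'
#' @return Tibble with columns `marker_id`, `x`, `y` (`rows * cols` rows,
#'   row-major ordering). Deterministic.
#' @export
place_marker_grid <- function(width, height, rows = 5, cols = 6, margin = 40) {
  stopifnot(rows >= 1, cols >= 1, margin >= 0)
  if (width - 2 * margin < 0 || height - 2 * margin < 0 ||
      (cols > 1 && width <= 2 * margin) || (rows > 1 && height <= 2 * margin))
    abort(sprintf("grid does not fit: need frame at least %g x %g px",
                  2 * margin + cols - 1, 2 * margin + rows - 1))
  xs <- if (cols == 1) (width + 1) / 2 else seq(margin, width - margin, length.out = cols)
  ys <- if (rows == 1) (height + 1) / 2 else seq(margin, height - margin, length.out = rows)
  g <- expand.grid(x = xs, y = ys)
  tibble(marker_id = seq_len(nrow(g)), x = g$x, y = g$y)
}

#' Track one spot through an image stack by normalized cross-correlation
#'
#' The template is cut once from the first frame around `init` (static
#' template: recordings are short and illumination constant). On every later
#' frame the template is correlated over a search window centered on the
#' previous position; the integer-pixel correlation peak is refined by
#' 3-point parabolic interpolation independently in x and y. Frames whose
#' peak correlation falls below `quality_floor` are marked lost and hold the
#' last position, keeping the series length uniform for differentiation.
#'
#' @param stack `height x width x n_frames` array (see [render_frames()]).
#' @param init Initial position `c(x, y)` on frame 1.
#' @param template_radius Template half-size, px (window is `2r + 1` square).
#' @param search_radius Search half-size around the previous position, px.
#' @param quality_floor Minimum acceptable peak correlation.
#' @param fs Sampling rate used for the `t_s` column; taken from
#'   `attr(stack, "fs")` when absent.
#'
#' @return Tibble with columns `frame`, `t_s`, `x_px`, `y_px`, `quality`,
#'   `lost`; `attr(, "valid")` is `FALSE` when more than 20% of frames were
#'   lost.
#' @export
track_spot <- function(stack, init, template_radius = 8, search_radius = 10,
                       quality_floor = 0.2, fs = NULL) {
  d <- dim(stack)
  if (length(d) != 3) abort("stack must be a height x width x n_frames array")
  if (d[3] < 2) abort("at least 2 frames required")
  fs <- fs %||% attr(stack, "fs") %||% NA_real_
  res <- ncc_track_cpp(stack, init[1], init[2],
                       as.integer(template_radius), as.integer(search_radius),
                       quality_floor)
  n <- d[3]
  out <- tibble(
    frame = seq_len(n),
    t_s = (seq_len(n) - 1) / fs,
    x_px = res$x, y_px = res$y,
    quality = res$quality, lost = res$lost
  )
  n_lost <- sum(res$lost)
  if (n_lost > 0)
    warn(sprintf("%d of %d frames lost (peak correlation < %g); holding last position",
                 n_lost, n, quality_floor))
  attr(out, "valid") <- n_lost <= 0.2 * n
  out
}

#' Track every grid marker through a stack
#'
#' @inheritParams track_spot
#' @param grid Marker grid tibble from [place_marker_grid()].
#' @return Trajectory tibble (`marker_id`, `frame`, `t_s`, `x_px`, `y_px`,
#'   `quality`, `lost`) preserving marker order, with a per-marker quality
#'   report in `attr(, "report")` (mean correlation, lost-frame count,
#'   validity). Errors if more than half of the markers are invalid.
#' @export
track_all <- function(stack, grid, template_radius = 8, search_radius = 10,
                      quality_floor = 0.2, fs = NULL) {
  fs <- fs %||% attr(stack, "fs") %||% NA_real_
  trajs <- purrr::map(seq_len(nrow(grid)), function(m) {
    tr <- suppressWarnings(track_spot(stack, c(grid$x[m], grid$y[m]),
                                      template_radius, search_radius,
                                      quality_floor, fs))
    tr$marker_id <- grid$marker_id[m]
    tr
  })
  report <- tibble(
    marker_id = grid$marker_id,
    mean_quality = purrr::map_dbl(trajs, ~ mean(.x$quality)),
    n_lost = purrr::map_int(trajs, ~ sum(.x$lost)),
    valid = purrr::map_lgl(trajs, ~ attr(.x, "valid"))
  )
  if (sum(!report$valid) > 0.5 * nrow(report))
    abort(sprintf("tracking failed: %d of %d markers invalid (> 50%%)",
                  sum(!report$valid), nrow(report)))
  out <- dplyr::bind_rows(trajs)
  out <- dplyr::select(out, "marker_id", dplyr::everything())
  attr(out, "fs") <- fs
  attr(out, "report") <- report
  out
}

#' Write a per-video tracking-quality report as JSON
#'
#' @param trajectories Output of [track_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracking_report <- function(trajectories, path) {
  rep <- attr(trajectories, "report")
  if (is.null(rep)) abort("no tracking report attached to these trajectories")
  jsonlite::write_json(rep, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
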