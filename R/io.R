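#' Read and write marker-trajectory tables
#'
#' The on-disk schema is a plain CSV with header
#' `marker_id,frame,t_s,x_px,y_px`, one row per marker per frame, UTF-8 with
#' dot decimal separator. `write_trajectories()` prints coordinates with six
#' decimals, so a write/read round trip reproduces coordinates to 1e-6 px
#' and a read/write round trip of a canonical file is byte-identical.
#'
#' @param ts Trajectory tibble (`marker_id`, `frame`, `t_s`, `x_px`, `y_px`).
#' @param path File path.
#' @return `read_trajectories()` returns the trajectory tibble with
#'   `attr(, "fs")` recovered from the timestamps; `write_trajectories()`
#'   returns `path` invisibly.
#' @export
write_trajectories <- function(ts, path) {
  need <- c("marker_id", "frame", "t_s", "x_px", "y_px")
  if (!all(need %in% names(ts)))
    abort(paste("trajectory table must have columns", paste(need, collapse = ", ")))
  out <- data.frame(
    marker_id = as.integer(ts$marker_id),
    frame = as.integer(ts$frame),
    t_s = sprintf("%.6f", ts$t_s),
    x_px = sprintf("%.6f", ts$x_px),
    y_px = sprintf("%.6f", ts$y_px)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  ts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("marker_id", "frame", "t_s", "x_px", "y_px")
  missing_cols <- setdiff(need, names(ts))
  if (length(missing_cols) > 0)
    abort(paste0("missing trajectory columns: ", paste(missing_cols, collapse = ", ")))
  ts <- ts[need]
  # per-marker frame numbering must be gapless and uniform
  by_marker <- split(ts, ts$marker_id)
  len <- vapply(by_marker, nrow, integer(1))
  if (length(unique(len)) != 1)
    abort("markers have different numbers of frames")
  for (m in names(by_marker)) {
    fr <- by_marker[[m]]$frame
    gap <- which(diff(fr) != 1)
    if (length(gap) > 0)
      abort(sprintf("gap in frame numbering for marker %s after frame %d",
                    m, fr[gap[1]]))
  }
  tt <- by_marker[[1]]$t_s
  dt <- diff(tt)
  if (length(dt) > 0 && (any(dt <= 0) || diff(range(dt)) > 1e-6))
    abort("timestamps are not uniformly increasing")
  attr(ts, "fs") <- if (length(dt) > 0) 1 / median(dt) else NA_real_
  as_tibble(ts)
}
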