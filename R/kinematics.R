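#' Scalar contraction displacement of each marker
#'
#' Displacement is the Euclidean distance of a marker from its reference
#' position, a single non-negative quantity per frame. The default reference
#' is the frame-1 position (where markers are placed); the `"baseline"`
#' policy averages the marker position over the decile of frames closest to
#' diastolic rest (the frames with the smallest preliminary first-frame
#' displacement), a robust reference for recordings whose first frame falls
#' mid-beat. A fixed coordinate percentile would pick the contracted
#' extreme, not rest, for markers whose coordinates decrease during
#' contraction.
#'
#' @param traj Trajectory tibble (`marker_id`, `frame`, `t_s`, `x_px`,
#'   `y_px`).
#' @param ref_policy `"first_frame"` (default) or `"baseline"`.
#' @return Tibble with columns `marker_id`, `frame`, `t_s`, `d_px`.
#' @export
displacement <- function(traj, ref_policy = c("first_frame", "baseline")) {
  ref_policy <- match.arg(ref_policy)
  ref_fun <- function(x, y) {
    if (ref_policy == "first_frame") return(c(x[1], y[1]))
    d0 <- sqrt((x - x[1])^2 + (y - y[1])^2)
    rest <- order(d0)[seq_len(max(1, ceiling(0.1 * length(x))))]
    c(mean(x[rest]), mean(y[rest]))
  }
  out <- traj |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::mutate(
      d_px = {
        r <- ref_fun(.data$x_px, .data$y_px)
        sqrt((.data$x_px - r[1])^2 + (.data$y_px - r[2])^2)
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("marker_id", "frame", "t_s", "d_px")
  attr(out, "fs") <- attr(traj, "fs")
  out
}

# Savitzky-Golay filter triple (smooth, d/dt, d2/dt2) for a given order,
# window and sampling rate. Filters come from signal::sgolay so that edge
# frames use the one-sided fit rows.
sg_filters <- function(polyorder, n, fs) {
  list(
    s = signal::sgolay(p = polyorder, n = n, m = 0, ts = 1 / fs),
    v = signal::sgolay(p = polyorder, n = n, m = 1, ts = 1 / fs),
    a = signal::sgolay(p = polyorder, n = n, m = 2, ts = 1 / fs)
  )
}

sg_window_samples <- function(window_s, polyorder, fs, n_signal) {
  nmin <- polyorder + 2
  if (nmin %% 2 == 0) nmin <- nmin + 1
  n <- if (is.null(window_s)) nmin else round(window_s * fs)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, nmin)
  if (n > n_signal)
    abort(sprintf("smoothing window (%d samples) exceeds the signal length %d; admissible windows span %d..%d samples",
                  n, n_signal, nmin, if (n_signal %% 2 == 1) n_signal else n_signal - 1))
  as.integer(n)
}

#' Local-polynomial smoothing and differentiation of displacement signals
#'
#' Fits a local polynomial of order `polyorder` (Savitzky-Golay) over a
#' sliding window and evaluates the fit and its first and second analytic
#' derivatives at every sample; edge frames use one-sided fits. The default
#' is a quartic over 7 samples (0.14 s at the default 50 Hz), the narrowest
#' symmetric quartic window: wider windows visibly attenuate the
#' acceleration peak of a 0.2 s contraction phase, while lower orders cannot
#' follow its curvature (see the methods vignette).
#'
#' @param d Displacement tibble from [displacement()] (column `d_px`).
#' @param fs Sampling rate, Hz; defaults to `attr(d, "fs")`.
#' @param window_s Window length in seconds; `NULL` (default) uses the
#'   minimal odd window of `polyorder + 2` samples, rounded up to odd.
#' @param polyorder Local polynomial order (default 4).
#' @return The input tibble with added columns `d_s` (smoothed displacement,
#'   px), `v` (px/s) and `a` (px/s^2).
#' @export
smooth_and_differentiate <- function(d, fs = NULL, window_s = NULL, polyorder = 4) {
  fs <- fs %||% attr(d, "fs")
  if (is.null(fs) || is.na(fs)) abort("sampling rate fs is required")
  n_sig <- sum(d$marker_id == d$marker_id[1])
  n <- sg_window_samples(window_s, polyorder, fs, n_sig)
  flt <- sg_filters(polyorder, n, fs)
  out <- d |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::mutate(
      d_s = signal::sgolayfilt(.data$d_px, flt$s),
      v = signal::sgolayfilt(.data$d_px, flt$v),
      a = signal::sgolayfilt(.data$d_px, flt$a)
    ) |>
    dplyr::ungroup()
  attr(out, "fs") <- fs
  out
}

# Apply one Savitzky-Golay filter matrix to every column of X, reproducing
# signal::sgolayfilt() semantics (central row convolved over the interior,
# one-sided rows at the edges) in three vectorized operations.
apply_sg <- function(X, F) {
  X <- as.matrix(X)
  nw <- nrow(F); k <- (nw - 1) / 2
  n <- nrow(X)
  Z <- stats::filter(X, rev(F[k + 1, ]), method = "convolution", sides = 2)
  Z <- matrix(as.numeric(Z), n, ncol(X))
  Z[1:k, ] <- F[1:k, , drop = FALSE] %*% X[1:nw, , drop = FALSE]
  Z[(n - k + 1):n, ] <- F[(k + 2):nw, , drop = FALSE] %*% X[(n - nw + 1):n, , drop = FALSE]
  Z
}

# -- beat detection -----------------------------------------------------------

#' Segment a displacement signal into beats
#'
#' Peaks are local maxima of the smoothed displacement with topographic
#' prominence at least `min_prominence` and mutual separation at least
#' `min_period_s` (closer peaks are merged into the higher one). Onset and
#' end are the signal minima between consecutive retained peaks. Beats whose
#' flank is truncated by the record edge are discarded.
#'
#' The default prominence floor is four times a robust noise scale:
#' `mad(diff(raw))`, the MAD of the first differences of the *unsmoothed*
#' displacement. A prominence is a difference between two (nearly
#' independently) noisy samples, so the relevant noise scale already carries
#' the sqrt(2) of a difference — hence no division. For a quiescent signal
#' this floor tracks the frame-to-frame tracking noise; for a beating signal
#' with a high duty cycle the first differences become slope-dominated,
#' keeping the floor proportional to the beat amplitude and well below the
#' beat prominence in both regimes. A noiseless signal that rests more than
#' half the time has `mad(diff) = 0`, so the floor never drops below 5% of
#' the signal range (which rejects filter ripple but no physiological
#' beat).
#'
#' @param x Numeric vector: smoothed displacement of one marker (or a tibble
#'   from [smooth_and_differentiate()], in which case all markers are
#'   segmented and a `marker_id` column is returned).
#' @param fs Sampling rate, Hz.
#' @param min_prominence Prominence floor, px; `NULL` for the adaptive
#'   default.
#' @param min_period_s Minimum peak separation, s.
#' @param raw Unsmoothed displacement used for the adaptive noise floor;
#'   defaults to `x` itself (pass the raw signal when `x` is smoothed, as
#'   [analyze_trajectories()] does).
#' @return Tibble of beat segments: `onset`, `peak`, `end` (frame indices),
#'   `prominence` (px). Zero rows when no peaks qualify.
#' @export
detect_beats <- function(x, fs, min_prominence = NULL, min_period_s = 0.25,
                         raw = NULL) {
  if (is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs")
    segs <- x |>
      dplyr::group_by(.data$marker_id) |>
      dplyr::reframe(detect_beats(.data$d_s, fs, min_prominence, min_period_s,
                                  raw = .data$d_px))
    return(segs)
  }
  n <- length(x)
  if (n < 3) abort("signal too short for beat detection (need >= 3 samples)")
  if (is.null(min_prominence)) {
    min_prominence <- default_prominence(x, raw %||% x)
  }
  segs <- beat_segments_cpp(x, min_prominence, as.integer(round(min_period_s * fs)))
  tibble(onset = segs$onset, peak = segs$peak, end = segs$end,
         prominence = segs$prominence)
}

default_prominence <- function(x, raw) {
  max(4 * mad(diff(raw)), 0.05 * diff(range(x)))
}

empty_segments <- function() {
  tibble(onset = integer(0), peak = integer(0), end = integer(0),
         prominence = numeric(0))
}

#' Per-beat contraction metrics
#'
#' For each beat: `D` is the smoothed displacement rise from onset to peak
#' (maximum contraction displacement, px); `V` is the maximum velocity over
#' the contraction phase onset..peak (contractility, px/s); `Acc` is the
#' maximum acceleration over the same phase (px/s^2). All are clipped below
#' at zero. Relaxation is deliberately excluded.
#'
#' @param d_s,v,a Numeric vectors: smoothed displacement and its
#'   derivatives for one marker.
#' @param segments Beat segments from [detect_beats()].
#' @return Tibble with `beat`, `D_px`, `V_px_s`, `Acc_px_s2`.
#' @export
beat_metrics <- function(d_s, v, a, segments) {
  k <- nrow(segments)
  if (k == 0)
    return(tibble(beat = integer(0), D_px = numeric(0), V_px_s = numeric(0),
                  Acc_px_s2 = numeric(0)))
  m <- beat_metrics_cpp(d_s, v, a, segments$onset, segments$peak)
  if (m$degenerate) warn("degenerate beat segment (onset == peak): metrics set to 0")
  tibble(beat = seq_len(k), D_px = m$D, V_px_s = m$V, Acc_px_s2 = m$Acc)
}

#' Full kinematic analysis of one video's trajectories
#'
#' Chains [displacement()], [smooth_and_differentiate()], [detect_beats()]
#' and [beat_metrics()] over every marker.
#'
#' @param traj Trajectory tibble.
#' @inheritParams smooth_and_differentiate
#' @inheritParams detect_beats
#' @param ref_policy Reference policy for [displacement()].
#' @return Tidy per-beat record tibble: `marker_id`, `beat`, `D_px`,
#'   `V_px_s`, `Acc_px_s2`.
#' @export
analyze_trajectories <- function(traj, fs = NULL, ref_policy = "first_frame",
                                 window_s = NULL, polyorder = 4,
                                 min_prominence = NULL, min_period_s = 0.25) {
  fs <- fs %||% attr(traj, "fs")
  if (is.null(fs) || is.na(fs)) abort("sampling rate fs is required")
  sm <- smooth_and_differentiate(displacement(traj, ref_policy), fs,
                                 window_s, polyorder)
  sm |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::reframe({
      segs <- detect_beats(.data$d_s, fs, min_prominence, min_period_s,
                           raw = .data$d_px)
      beat_metrics(.data$d_s, .data$v, .data$a, segs)
    })
}

#' Aggregate per-beat records to one video
#'
#' Records are averaged per marker over its beats, then over markers
#' (markers with no detected beat do not contribute).
#'
#' @param records Per-beat record tibble from [analyze_trajectories()].
#' @return One-row tibble: `D_px`, `V_px_s`, `Acc_px_s2`, `n_markers`,
#'   `n_beats`.
#' @export
summarize_video <- function(records) {
  if (nrow(records) == 0) abort("no beats detected in this video")
  g <- factor(records$marker_id)
  nb <- tabulate(g)
  sums <- rowsum(cbind(records$D_px, records$V_px_s, records$Acc_px_s2), g)
  per_marker <- sums / nb
  tibble(
    D_px = mean(per_marker[, 1]), V_px_s = mean(per_marker[, 2]),
    Acc_px_s2 = mean(per_marker[, 3]),
    n_markers = nrow(per_marker), n_beats = sum(nb)
  )
}

#' Aggregate video summaries to one syncytium
#'
#' Unweighted mean of the video-level metrics over the acquisitions in the
#' analysis window (27-39 min in the modelled design).
#'
#' @param video_summaries Tibble of video summaries (one row per acquisition,
#'   columns `D_px`, `V_px_s`, `Acc_px_s2`, `n_beats`).
#' @return One-row tibble: `D_mean`, `V_mean`, `Acc_mean`, `n_videos`,
#'   `n_beats`.
#' @export
summarize_syncytium <- function(video_summaries) {
  if (nrow(video_summaries) == 0) abort("no video summaries in the analysis window")
  tibble(
    D_mean = mean(video_summaries$D_px),
    V_mean = mean(video_summaries$V_px_s),
    Acc_mean = mean(video_summaries$Acc_px_s2),
    n_videos = nrow(video_summaries),
    n_beats = sum(video_summaries$n_beats)
  )
}

# Fast matrix path used by the study pipeline: displacement, SG filtering and
# beat metrics on n_frames x M coordinate matrices, avoiding per-video tibble
# reshaping. Returns the per-beat records tibble.
analyze_matrices <- function(X, Y, fs, window_s = NULL, polyorder = 4,
                             min_prominence = NULL, min_period_s = 0.25) {
  n <- nrow(X); M <- ncol(X)
  D <- sqrt(sweep(X, 2, X[1, ])^2 + sweep(Y, 2, Y[1, ])^2)
  nw <- sg_window_samples(window_s, polyorder, fs, n)
  flt <- sg_filters(polyorder, nw, fs)
  DS <- apply_sg(D, flt$s)
  V <- apply_sg(D, flt$v)
  A <- apply_sg(D, flt$a)
  min_gap <- as.integer(round(min_period_s * fs))
  mk <- dd <- vv <- aa <- vector("list", M)
  for (m in seq_len(M)) {
    prom <- min_prominence %||% default_prominence(DS[, m], D[, m])
    segs <- beat_segments_cpp(DS[, m], prom, min_gap)
    if (length(segs$peak) == 0) next
    bm <- beat_metrics_cpp(DS[, m], V[, m], A[, m], segs$onset, segs$peak)
    mk[[m]] <- rep.int(m, length(segs$peak))
    dd[[m]] <- bm$D; vv[[m]] <- bm$V; aa[[m]] <- bm$Acc
  }
  mk <- unlist(mk); if (is.null(mk)) mk <- integer(0)
  tibble(
    marker_id = mk,
    beat = if (length(mk)) sequence(rle(mk)$lengths) else integer(0),
    D_px = as.numeric(unlist(dd)), V_px_s = as.numeric(unlist(vv)),
    Acc_px_s2 = as.numeric(unlist(aa))
  )
}
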