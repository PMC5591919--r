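#' Uniform sampling grid of a video recording
#'
#' @param fs Sampling (frame) rate in Hz. The default of 50 Hz is chosen so
#'   that the second derivative of the contraction pulse is resolvable by
#'   local-polynomial differentiation (see the methods vignette).
#' @param duration Recording duration in seconds (20 s recordings by default,
#'   matching the study design).
#' @param n_frames Number of frames; overrides `duration` when given.
#'
#' @return A `time_base` object with fields `fs`, `n_frames`, `duration` and
#'   a `t()`-like accessor via [frame_times()].
#' @export
time_base <- function(fs = 50, duration = 20, n_frames = NULL) {
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  n <- if (is.null(n_frames)) as.integer(round(duration * fs)) else as.integer(n_frames)
  if (n < 2) abort("a time base needs at least 2 frames")
  structure(list(fs = fs, n_frames = n, duration = n / fs), class = "time_base")
}

#' Frame timestamps of a time base
#'
#' Timestamps are uniform, `t_i = i / fs` for `i = 0, ..., n_frames - 1`.
#'
#' @param tb A [time_base()].
#' @return Numeric vector of length `n_frames`.
#' @export
frame_times <- function(tb) (seq_len(tb$n_frames) - 1) / tb$fs

#' @export
print.time_base <- function(x, ...) {
  cat(sprintf("<time_base> fs = %g Hz, %d frames, %.3g s\n", x$fs, x$n_frames, x$duration))
  invisible(x)
}

#' Parameters of the synthetic contraction waveform
#'
#' One beat is a raised-cosine pulse: the displacement rises as
#' `(1 - cos(pi * u / tau_c)) / 2` during the contraction phase
#' (`u` in `[0, tau_c]`) and falls as `(1 + cos(pi * (u - tau_c) / tau_r)) / 2`
#' during relaxation. Both derivatives are closed-form, so the generator
#' carries exact ground truth for peak displacement, velocity and
#' acceleration.
#'
#' @param A0 Peak contraction displacement of the farthest marker, pixels.
#' @param f_beat Spontaneous beat rate, Hz (murine syncytia beat at ~1-3 Hz).
#' @param tau_c Contraction-phase duration, s.
#' @param tau_r Relaxation-phase duration, s.
#' @param jitter_cv Coefficient of variation of the beat-to-beat interval.
#' @param noise_sigma Additive per-frame positional noise, px (tracker jitter).
#' @param drift Linear drift rate, px/s, applied along the x axis.
#'
#' @return A `beat_waveform_params` list.
#' @export
beat_waveform_params <- function(A0 = 10, f_beat = 1.5, tau_c = 0.2, tau_r = 0.3,
                                 jitter_cv = 0.1, noise_sigma = 0.1, drift = 0) {
  stopifnot(A0 >= 0, f_beat > 0, tau_c > 0, tau_r > 0, noise_sigma >= 0)
  if (jitter_cv < 0 || jitter_cv > 0.5) abort("jitter_cv must lie in [0, 0.5]")
  if (tau_c + tau_r > 1 / f_beat + 1e-12)
    abort("pulse duration tau_c + tau_r must not exceed the beat period 1/f_beat")
  structure(list(A0 = A0, f_beat = f_beat, tau_c = tau_c, tau_r = tau_r,
                 jitter_cv = jitter_cv, noise_sigma = noise_sigma, drift = drift),
            class = "beat_waveform_params")
}

# Closed-form pulse and derivatives at phase u (u = 0 at contraction onset).
pulse_s <- function(u, tau_c, tau_r) {
  s <- numeric(length(u))
  i1 <- u >= 0 & u <= tau_c
  i2 <- u > tau_c & u <= tau_c + tau_r
  s[i1] <- (1 - cos(pi * u[i1] / tau_c)) / 2
  s[i2] <- (1 + cos(pi * (u[i2] - tau_c) / tau_r)) / 2
  s
}

pulse_sdot <- function(u, tau_c, tau_r) {
  s <- numeric(length(u))
  i1 <- u >= 0 & u <= tau_c
  i2 <- u > tau_c & u <= tau_c + tau_r
  s[i1] <- pi / (2 * tau_c) * sin(pi * u[i1] / tau_c)
  s[i2] <- -pi / (2 * tau_r) * sin(pi * (u[i2] - tau_c) / tau_r)
  s
}

pulse_sddot <- function(u, tau_c, tau_r) {
  s <- numeric(length(u))
  i1 <- u >= 0 & u <= tau_c
  i2 <- u > tau_c & u <= tau_c + tau_r
  s[i1] <- pi^2 / (2 * tau_c^2) * cos(pi * u[i1] / tau_c)
  s[i2] <- -pi^2 / (2 * tau_r^2) * cos(pi * (u[i2] - tau_c) / tau_r)
  s
}

# Analytic maxima of the pulse and its derivatives (unit amplitude).
pulse_maxima <- function(tau_c) {
  c(s = 1, s_dot = pi / (2 * tau_c), s_ddot = pi^2 / (2 * tau_c^2))
}

# Draw beat onset times over [0, duration). First onset at half a period,
# subsequent intervals 1/f_beat * (1 + jitter_cv * z); intervals are clamped
# below at tau_c + tau_r so that pulses never overlap.
draw_beat_times <- function(p, duration) {
  period <- 1 / p$f_beat
  t0 <- period / 2 + if (p$jitter_cv > 0) rnorm(1, 0, p$jitter_cv * period) else 0
  t0 <- max(t0, 0)
  onsets <- numeric(0)
  tcur <- t0
  clamped <- FALSE
  while (tcur < duration) {
    onsets <- c(onsets, tcur)
    gap <- period * (1 + if (p$jitter_cv > 0) p$jitter_cv * rnorm(1) else 0)
    if (gap < p$tau_c + p$tau_r) {
      gap <- p$tau_c + p$tau_r
      clamped <- TRUE
    }
    tcur <- tcur + gap
  }
  if (clamped) warn("beat intervals clamped to tau_c + tau_r to keep pulses disjoint")
  onsets
}

#' Generate the unitless contraction waveform and its exact derivatives
#'
#' Produces `s(t) = sum_k pulse(t - T_k)` sampled at the frame times of `tb`,
#' together with the exact analytic first and second derivatives and the
#' realized beat (pulse-onset) times.
#'
#' @param p A [beat_waveform_params()] (only the temporal fields are used;
#'   `A0` scales trajectories, not `s`).
#' @param tb A [time_base()].
#' @param seed Optional integer seed for the beat-interval jitter.
#'
#' @return A tibble with columns `t_s`, `s`, `s_dot`, `s_ddot`; the realized
#'   onset times are in `attr(, "beat_times")`.
#' @export
make_beat_waveform <- function(p, tb, seed = NULL) {
  stopifnot(inherits(p, "beat_waveform_params"), inherits(tb, "time_base"))
  if (!is.null(seed)) set.seed(seed)
  t <- frame_times(tb)
  onsets <- draw_beat_times(p, tb$duration)
  out <- waveform_at(t, onsets, p)
  res <- tibble(t_s = t, s = out$s, s_dot = out$s_dot, s_ddot = out$s_ddot)
  attr(res, "beat_times") <- onsets
  res
}

# Evaluate s and derivatives at times t for given disjoint pulse onsets.
waveform_at <- function(t, onsets, p) {
  s <- sdot <- sddot <- numeric(length(t))
  if (length(onsets) > 0) {
    idx <- findInterval(t, onsets)
    has <- idx > 0
    u <- t[has] - onsets[idx[has]]
    s[has] <- pulse_s(u, p$tau_c, p$tau_r)
    sdot[has] <- pulse_sdot(u, p$tau_c, p$tau_r)
    sddot[has] <- pulse_sddot(u, p$tau_c, p$tau_r)
  }
  list(s = s, s_dot = sdot, s_ddot = sddot)
}
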