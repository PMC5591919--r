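# Shared fixtures, all built in code.

# Default-size grid on the study frame, with its contraction center and the
# id of the farthest marker (the ground-truth carrier).
study_grid <- function() {
  g <- place_marker_grid(640, 480, 5, 6, 60)
  center <- c(mean(g$x), mean(g$y))
  far <- g$marker_id[which.max((g$x - center[1])^2 + (g$y - center[2])^2)]
  list(grid = g, center = center, far = far)
}

# Noise-free, jitter-free waveform parameters used by the analytic checks.
clean_params <- function(A0 = 10, f_beat = 1, tau_c = 0.2, tau_r = 0.3) {
  beat_waveform_params(A0 = A0, f_beat = f_beat, tau_c = tau_c, tau_r = tau_r,
                       jitter_cv = 0, noise_sigma = 0, drift = 0)
}

# Dense numerical oracle for the pulse maxima: evaluate the closed-form
# pulse on a 100 kHz grid, independent of the generator's sampling path.
dense_pulse_maxima <- function(tau_c, tau_r) {
  u <- seq(0, tau_c + tau_r, by = 1e-5)
  s <- ifelse(u <= tau_c, (1 - cos(pi * u / tau_c)) / 2,
              (1 + cos(pi * (u - tau_c) / tau_r)) / 2)
  ds <- diff(s) / 1e-5
  dds <- diff(ds) / 1e-5
  c(s = max(s), s_dot = max(ds), s_ddot = max(dds))
}

# Long-format sinusoidal single-axis trajectory for tracking / kinematics
# oracles.
sinusoid_trajectories <- function(grid, n, fs, amplitude = 5, freq = 1) {
  t <- (seq_len(n) - 1) / fs
  out <- tidyr::crossing(marker_id = grid$marker_id, frame = seq_len(n))
  out <- dplyr::left_join(out, grid, by = "marker_id")
  out <- dplyr::mutate(out, t_s = (frame - 1) / fs,
                       x_px = x + amplitude * sin(2 * pi * freq * t_s),
                       y_px = y)
  out <- dplyr::select(out, marker_id, frame, t_s, x_px, y_px)
  attr(out, "fs") <- fs
  out
}
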