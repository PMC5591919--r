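#' Per-arm condition effects of the synthetic study
#'
#' Each experimental arm acts multiplicatively on the base waveform:
#' `amp_mult` scales the contraction amplitude, `tau_mult` scales both phase
#' durations (a shortened contraction raises peak velocity ~ A/tau and peak
#' acceleration ~ A/tau^2 more than displacement), and `rate_mult` scales the
#' beat rate. `between_cv` is the lognormal coefficient of variation of the
#' syncytium-to-syncytium amplitude factor.
#'
#' @param condition One of `"CTRL"`, `"ISO"`, `"EMF"`, `"ISO+EMF"`.
#' @param amp_mult,tau_mult,rate_mult Positive multipliers.
#' @param between_cv Inter-syncytium multiplicative variability, in `[0, 1)`.
#' @return A `condition_params` list.
#' @export
condition_params <- function(condition, amp_mult = 1, tau_mult = 1,
                             rate_mult = 1, between_cv = 0.2) {
  condition <- match.arg(condition, ARM_LEVELS)
  stopifnot(amp_mult > 0, tau_mult > 0, rate_mult > 0,
            between_cv >= 0, between_cv < 1)
  structure(list(condition = condition, amp_mult = amp_mult,
                 tau_mult = tau_mult, rate_mult = rate_mult,
                 between_cv = between_cv),
            class = "condition_params")
}

#' Default effects of the four study arms
#'
#' Defaults are calibrated by power analysis so that, with `n = 20` syncytia
#' per arm and 20% between-syncytium variability, displacement contrasts
#' against control are significant only for the combined arm while
#' acceleration contrasts are significant for every arm — the
#' kinematics-versus-dynamics dissociation of the modelled experiment.
#' Amplitude effects against control must stay within about +/-6% to remain
#' reliably nonsignificant at this design (LSD threshold ~12.6% of the
#' control mean), while the tau shortening under beta-adrenergic stimulation
#' amplifies acceleration (~ A/tau^2) far beyond it; see the methods
#' vignette for the calibration.
#'
#' @param between_cv Shared inter-syncytium CV.
#' @return Named list of [condition_params()], one per arm.
#' @export
default_conditions <- function(between_cv = 0.2) {
  list(
    "CTRL"    = condition_params("CTRL",    1.00, 1.00, 1.00, between_cv),
    "ISO"     = condition_params("ISO",     1.04, 0.80, 1.15, between_cv),
    "EMF"     = condition_params("EMF",     0.96, 1.10, 0.95, between_cv),
    "ISO+EMF" = condition_params("ISO+EMF", 0.75, 1.15, 0.90, between_cv)
  )
}

# Waveform parameters of one arm: multipliers applied to the base parameters.
apply_condition <- function(base, cp) {
  beat_waveform_params(
    A0 = base$A0 * cp$amp_mult,
    f_beat = base$f_beat * cp$rate_mult,
    tau_c = base$tau_c * cp$tau_mult,
    tau_r = base$tau_r * cp$tau_mult,
    jitter_cv = base$jitter_cv,
    noise_sigma = base$noise_sigma,
    drift = base$drift
  )
}

# Matrix core of the trajectory generator: returns X, Y (n_frames x M),
# the per-marker amplitudes and the waveform. Used by synth_trajectories()
# and by the streaming study simulator.
synth_core <- function(cp, base, grid, center, tb, syncytium_factor = NULL) {
  M <- nrow(grid)
  if (M < 1) abort("empty grid: at least one marker is required")
  eff <- apply_condition(base, cp)
  if (is.null(syncytium_factor)) {
    syncytium_factor <- draw_syncytium_factor(cp$between_cv)
  }
  A_syn <- eff$A0 * syncytium_factor

  onsets <- draw_beat_times(eff, tb$duration)
  t <- frame_times(tb)
  wf <- waveform_at(t, onsets, eff)

  dx <- center[1] - grid$x
  dy <- center[2] - grid$y
  dist <- sqrt(dx^2 + dy^2)
  dmax <- max(dist)
  if (dmax == 0) {
    ex <- ey <- rep(0, M)
    A_m <- rep(0, M)
  } else {
    ex <- ifelse(dist > 0, dx / dist, 0)
    ey <- ifelse(dist > 0, dy / dist, 0)
    A_m <- A_syn * dist / dmax
  }

  n <- tb$n_frames
  X <- outer(wf$s, A_m * ex) # displacement toward center
  Y <- outer(wf$s, A_m * ey)
  X <- sweep(X, 2, grid$x, function(m, r) r + m)
  Y <- sweep(Y, 2, grid$y, function(m, r) r + m)
  if (eff$noise_sigma > 0) {
    X <- X + matrix(rnorm(n * M, 0, eff$noise_sigma), n, M)
    Y <- Y + matrix(rnorm(n * M, 0, eff$noise_sigma), n, M)
  }
  if (eff$drift != 0) X <- X + eff$drift * t

  mx <- pulse_maxima(eff$tau_c)
  gt <- tibble(
    condition = cp$condition,
    A_max = A_syn,
    D_true = A_syn * mx[["s"]],
    V_true = A_syn * mx[["s_dot"]],
    Acc_true = A_syn * mx[["s_ddot"]],
    f_beat = eff$f_beat, tau_c = eff$tau_c, tau_r = eff$tau_r
  )
  attr(gt, "beat_times") <- onsets
  list(X = X, Y = Y, t = t, grid = grid, gt = gt, eff = eff)
}

draw_syncytium_factor <- function(cv) {
  if (cv <= 0) return(1)
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Synthesize marker trajectories for one video of one beating syncytium
#'
#' Marker `m` at rest position `r_m` moves radially toward `center` as
#' `r_m - A_m * s(t) * e_m` plus tracking noise and drift, where `e_m` is the
#' unit vector toward the center and `A_m` scales linearly with the rest
#' distance from the center (a sheet contracting about its centroid). The
#' farthest marker carries the ground-truth peak displacement, velocity and
#' acceleration, computed from the closed-form pulse maxima.
#'
#' @param cp A [condition_params()].
#' @param base A [beat_waveform_params()] describing the control waveform.
#' @param grid Data frame of marker rest positions with columns `x`, `y`
#'   (see [place_marker_grid()]).
#' @param center Contraction center `c(x, y)` in px; defaults to the grid
#'   centroid.
#' @param tb A [time_base()].
#' @param seed Optional integer seed.
#' @param syncytium_factor Optional precomputed lognormal amplitude factor,
#'   so several videos of the same syncytium share one draw.
#'
#' @return A tibble with columns `marker_id`, `frame`, `t_s`, `x_px`, `y_px`.
#'   Attributes: `ground_truth` (one-row tibble with `D_true`, `V_true`,
#'   `Acc_true`, realized beat times in its own attribute), `fs`,
#'   `condition`.
#' @export
synth_trajectories <- function(cp, base, grid, center = NULL, tb = time_base(),
                               seed = NULL, syncytium_factor = NULL) {
  stopifnot(inherits(cp, "condition_params"), inherits(base, "beat_waveform_params"))
  grid <- as_tibble(grid)
  if (!all(c("x", "y") %in% names(grid))) abort("grid needs columns x and y")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(center)) center <- c(mean(grid$x), mean(grid$y))
  core <- synth_core(cp, base, grid, center, tb, syncytium_factor)
  res <- trajectories_from_matrices(core$X, core$Y, core$t)
  attr(res, "ground_truth") <- core$gt
  attr(res, "fs") <- tb$fs
  attr(res, "condition") <- cp$condition
  res
}

# Long-format trajectory table from n x M coordinate matrices.
trajectories_from_matrices <- function(X, Y, t) {
  n <- nrow(X); M <- ncol(X)
  tibble(
    marker_id = rep(seq_len(M), each = n),
    frame = rep(seq_len(n), M),
    t_s = rep(t, M),
    x_px = as.vector(X),
    y_px = as.vector(Y)
  )
}

#' Ground truth attached to a synthetic trajectory set
#'
#' @param x A tibble returned by [synth_trajectories()].
#' @return One-row tibble with `D_true` (px), `V_true` (px/s), `Acc_true`
#'   (px/s^2) for the farthest marker.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")
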