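sg <- study_grid()

test_that("displacement is the distance from the reference and reproduces the waveform", {
  # constant trajectory -> identically zero
  ts0 <- tibble::tibble(marker_id = 1L, frame = 1:50, t_s = (0:49) / 50,
                        x_px = 100, y_px = 80)
  expect_true(all(displacement(ts0)$d_px == 0))
  # pure x-motion x0 - A s(t): displacement equals A s(t) exactly
  tb <- time_base(50, 5)
  wf <- make_beat_waveform(clean_params(), tb)
  ts <- tibble::tibble(marker_id = 1L, frame = seq_len(tb$n_frames),
                       t_s = wf$t_s, x_px = 100 - 10 * wf$s, y_px = 80)
  expect_equal(displacement(ts)$d_px, 10 * wf$s, tolerance = 1e-12)
})

test_that("baseline reference recovers diastole under drift", {
  tb <- time_base(50, 10)
  wf <- make_beat_waveform(clean_params(), tb)
  ts <- tibble::tibble(marker_id = 1L, frame = seq_len(tb$n_frames),
                       t_s = wf$t_s, x_px = 100 - 10 * wf$s, y_px = 80)
  d <- displacement(ts, ref_policy = "baseline")
  # 10th-percentile reference sits at the rest position (s = 0 most of the time)
  expect_lt(abs(max(d$d_px) - 10), 0.2)
})

test_that("constant input has zero smoothed derivatives", {
  d <- tibble::tibble(marker_id = 1L, frame = 1:100, t_s = (0:99) / 50,
                      d_px = 3.7)
  sm <- smooth_and_differentiate(d, fs = 50)
  expect_equal(sm$d_s, rep(3.7, 100), tolerance = 1e-10)
  expect_lt(max(abs(sm$v)), 1e-9)
  expect_lt(max(abs(sm$a)), 1e-9)
})

test_that("sinusoid derivatives match the analytic maxima (fs = 25)", {
  t <- (0:499) / 25
  d <- tibble::tibble(marker_id = 1L, frame = seq_along(t), t_s = t,
                      d_px = 10 + 10 * sin(2 * pi * t))
  sm <- smooth_and_differentiate(d, fs = 25)
  expect_equal(max(sm$v), 2 * pi * 10, tolerance = 0.02)   # 62.83 px/s
  expect_equal(max(sm$a), (2 * pi)^2 * 10, tolerance = 0.05) # 394.8 px/s^2
})

test_that("raised-cosine peak velocity is recovered at both the default and low frame rate", {
  peak_v <- function(fs, ...) {
    tb <- time_base(fs, 20)
    wf <- make_beat_waveform(clean_params(), tb)
    d <- tibble::tibble(marker_id = 1L, frame = seq_len(tb$n_frames),
                        t_s = wf$t_s, d_px = 10 * wf$s)
    max(smooth_and_differentiate(d, fs = fs, ...)$v)
  }
  expect_equal(peak_v(50), 78.53982, tolerance = 0.05)
  # at 25 Hz the 7-sample window spans 0.28 s; the quintic tracks the peak
  expect_equal(peak_v(25, polyorder = 5), 78.53982, tolerance = 0.05)
})

test_that("window validation reports the admissible range", {
  d <- tibble::tibble(marker_id = 1L, frame = 1:20, t_s = (0:19) / 50,
                      d_px = rnorm(20))
  expect_error(smooth_and_differentiate(d, fs = 50, window_s = 1), "admissible")
  expect_silent(smooth_and_differentiate(d, fs = 50, window_s = 0.3))
})

test_that("beat detection: flat and noise-only signals yield no beats", {
  expect_equal(nrow(detect_beats(rep(1, 100), 50)), 0)
  set.seed(1)
  d <- sqrt(rnorm(1000, 0, 0.1)^2 + rnorm(1000, 0, 0.1)^2)
  ds <- signal::sgolayfilt(d, signal::sgolay(4, 7, 0, 0.02))
  expect_equal(nrow(detect_beats(ds, 50, raw = d)), 0)
})

test_that("a 1 Hz noise-free generator yields 20 +/- 1 beats over 20 s", {
  tb <- time_base(50, 20)
  ts <- synth_trajectories(condition_params("CTRL"), clean_params(f_beat = 1),
                           sg$grid, center = sg$center, tb = tb, seed = 2,
                           syncytium_factor = 1)
  sm <- smooth_and_differentiate(displacement(ts), 50)
  far <- dplyr::filter(sm, marker_id == sg$far)
  segs <- detect_beats(far$d_s, 50, raw = far$d_px)
  expect_lte(abs(nrow(segs) - 20), 1)
  expect_true(all(segs$onset <= segs$peak & segs$peak <= segs$end))
  expect_true(all(diff(segs$peak) > 0))
})

test_that("peaks closer than the refractory period merge into one detection", {
  t <- (0:199) / 50
  x <- exp(-((t - 1)^2) / (2 * 0.03^2)) + 0.9 * exp(-((t - 1.1)^2) / (2 * 0.03^2))
  segs <- detect_beats(x, 50, min_prominence = 0.2, min_period_s = 0.25)
  expect_equal(nrow(segs), 1)
  segs2 <- detect_beats(x, 50, min_prominence = 0.2, min_period_s = 0.05)
  expect_equal(nrow(segs2), 2)
})

test_that("beat metrics recover the analytic pulse maxima at 100 Hz", {
  tb <- time_base(100, 20)
  ts <- synth_trajectories(condition_params("CTRL"), clean_params(),
                           sg$grid, center = sg$center, tb = tb, seed = 3,
                           syncytium_factor = 1)
  recs <- analyze_trajectories(ts, fs = 100)
  far <- dplyr::filter(recs, marker_id == sg$far)
  expect_equal(mean(far$D_px), 10, tolerance = 0.01)
  expect_equal(mean(far$V_px_s), 78.53982, tolerance = 0.02)
  expect_equal(mean(far$Acc_px_s2), 1233.701, tolerance = 0.05)
})

test_that("metrics scale linearly with amplitude and vanish at zero amplitude", {
  run <- function(A0) {
    ts <- synth_trajectories(condition_params("CTRL"), clean_params(A0 = A0),
                             sg$grid, center = sg$center,
                             tb = time_base(50, 10), seed = 4,
                             syncytium_factor = 1)
    recs <- analyze_trajectories(ts, fs = 50)
    if (nrow(recs) == 0) return(c(0, 0, 0))
    far <- dplyr::filter(recs, marker_id == sg$far)
    c(mean(far$D_px), mean(far$V_px_s), mean(far$Acc_px_s2))
  }
  expect_equal(run(0), c(0, 0, 0))
  expect_equal(run(16), 2 * run(8), tolerance = 1e-6)
})

test_that("degenerate segments yield zero metrics with a warning", {
  seg <- tibble::tibble(onset = 5L, peak = 5L, end = 9L, prominence = 1)
  expect_warning(bm <- beat_metrics(1:20, 1:20, 1:20, seg), "degenerate")
  expect_equal(c(bm$D_px, bm$V_px_s, bm$Acc_px_s2), c(0, 0, 0))
})

test_that("video and syncytium aggregation follow the documented order", {
  recs <- tibble::tibble(marker_id = c(1L, 1L, 2L), beat = c(1L, 2L, 1L),
                         D_px = c(2, 4, 6), V_px_s = 0, Acc_px_s2 = 0)
  vs <- summarize_video(recs)
  expect_equal(vs$D_px, 4.5) # mean(mean(2,4), 6)
  expect_equal(vs$n_beats, 3L)
  expect_error(summarize_video(recs[0, ]), "no beats")

  vids <- tibble::tibble(D_px = 1:5, V_px_s = 1, Acc_px_s2 = 1, n_beats = 10)
  ss <- summarize_syncytium(vids)
  expect_equal(ss$D_mean, 3)
  expect_equal(ss$n_videos, 5L)
  expect_error(summarize_syncytium(vids[0, ]), "no video summaries")
})

test_that("displacement is frame-rate invariant; derivatives within discretization error", {
  run <- function(fs) {
    ts <- synth_trajectories(condition_params("CTRL"), clean_params(),
                             sg$grid, center = sg$center,
                             tb = time_base(fs, 10), seed = 6,
                             syncytium_factor = 1)
    recs <- analyze_trajectories(ts, fs = fs)
    far <- dplyr::filter(recs, marker_id == sg$far)
    c(mean(far$D_px), mean(far$V_px_s), mean(far$Acc_px_s2))
  }
  a <- run(50); b <- run(100)
  expect_equal(a[1], b[1], tolerance = 0.02)
  expect_equal(a[2], b[2], tolerance = 0.05)
  expect_equal(a[3], b[3], tolerance = 0.15)
})

test_that("larger contraction amplitude raises recovered displacement (paired seeds)", {
  run <- function(amp, s) {
    ts <- suppressWarnings(synth_trajectories(
      condition_params("ISO", amp_mult = amp), beat_waveform_params(),
      sg$grid, center = sg$center, tb = time_base(50, 10), seed = s))
    vs <- summarize_video(analyze_trajectories(ts, fs = 50))
    vs$D_px
  }
  gains <- sapply(1:8, function(s) run(1.5, s) - run(1.0, s))
  expect_true(all(gains > 0))
})
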