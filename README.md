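# cardiokin

Video-based kinematic and dynamic analysis of spontaneously beating
cardiac syncytia — murine ventricular cardiomyocyte sheets in culture —
under β-adrenergic stimulation (10 µM isoproterenol, ISO), 75 Hz pulsed
electromagnetic field exposure (≈ 3 mT, EMF), and their combination.
The package is aimed at quantitative biologists who want a fully tested,
synthetic-data-driven re-implementation of this assay: every stage can be
exercised against generated data with exact ground truth, because the raw
videos of such experiments are rarely public.

## What it computes

For each marker on a 5 × 6 orthogonal grid, tracked frame by frame, the
scalar displacement `d(t) = ‖r(t) − r_ref‖` (pixels) is smoothed by a local
polynomial (Savitzky–Golay) fit whose analytic derivatives give velocity
and acceleration. Per detected beat:

* **D** — maximum contraction displacement, `d_s(peak) − d_s(onset)` [px]
* **V** — contractility, `max v(t)` over the contraction phase [px/s]
* **Acc** — contraction acceleration, `max a(t)` over the same phase [px/s²]

Beat → marker → video → syncytium means (acquisitions every 3 min over the
27–39 min window) yield one value per syncytium, the experimental unit of a
one-way ANOVA with Fisher LSD post-hoc comparisons: for groups *i, j* with
pooled error variance `MS_w`,

```
Δ_ij ± t(0.975, N−k) · sqrt(MS_w · (1/n_i + 1/n_j))
```

with significance decided by the 95% CI excluding zero (unadjusted, as LSD
is defined). A companion module models the exposure system — two coaxial
air-cored solenoids in series driven by a trapezoidal 0→319 mA / 1.36 ms
pulse at 75 Hz — via the elliptic-integral loop field: `B_Z` maps at the
culture plane, homogeneity, energy density `u = B²/2μ₀`, and the induced
azimuthal field `E = (r/2)·dB/dt`. A fluorescence module quantifies
synthetic sarcomeric-myosin (MF20-like) images and tests fold changes with
the same statistics.

The synthetic generator (raised-cosine beat pulses with closed-form
derivatives, radial contraction toward the sheet centroid, lognormal
between-syncytium variability, Gaussian tracking noise) defines the study
conditions: 4 arms × 20 syncytia × 5 videos of 20 s.

## Worked example

```r
library(cardiokin)

grid <- place_marker_grid(640, 480)          # the 30-marker registration grid
ts   <- synth_trajectories(condition_params("CTRL"), beat_waveform_params(),
                           grid, tb = time_base(), seed = 1)
recs <- analyze_trajectories(ts, fs = 50)
summarize_video(recs)
#> # A tibble: 1 × 5
#>    D_px V_px_s Acc_px_s2 n_markers n_beats
#>   <dbl>  <dbl>     <dbl>     <int>   <int>
#> 1  5.51   44.8      868.        30     870
```

This syncytium drew an amplitude factor below 1 (its ground truth is
`D_true = 8.66` px, `V_true = 68.0` px/s, `Acc_true = 1069` px/s² for the
farthest marker); the video means are lower because markers nearer the
contraction center move proportionally less — the per-marker metrics of the
farthest marker recover the ground truth to ~1% (D), ~1% (V), ~5% (Acc).

```r
field_report()
#>   B_center_mT homogeneity_pct u_J_m3 dBdt_T_s E_edge_mV_m
#> 1       2.832           1.226   3.19    2.082      18.218
```

The calibrated default coil pair delivers 2.83 mT at the culture midplane
("circa 3 mT"), a peak magnetic energy density of 3.19 J/m³, 1.2%
inhomogeneity over the central culture region, and 18.2 mV/m induced at the
edge of a 35 mm dish during the 1.36 ms ramp.

A full four-arm study and its significance patterns:

```r
summaries <- simulate_study_summaries(study_design(), seed = 1)
study_stats(summaries)$Acc_mean$pattern     # ISO up*, EMF down*, ISO+EMF down*
reproduce_patterns(n_seeds = 20, seed = 1)$verdict
```

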