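---
title: "Methods: kinematics and dosimetry of beating cardiac syncytia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics and dosimetry of beating cardiac syncytia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cardiokin` models a video-based contractility assay for spontaneously
beating neonatal murine cardiac syncytia under four conditions — untreated
control (CTRL), 10 µM isoproterenol (ISO), a 75 Hz pulsed electromagnetic
field of about 3 mT (EMF), and their combination (ISO+EMF). The pipeline
runs from marker trajectories (tracked or synthesized) through per-beat
contraction metrics to a one-way ANOVA with Fisher LSD confidence
intervals, plus a Biot–Savart model of the solenoid-pair bioreactor. This
vignette documents the models, the tunable parameters, and the design
choices that were genuinely open.

## The synthetic contraction model

A beat is a raised-cosine pulse in the unitless contraction coordinate
`s(t) ∈ [0, 1]`:

* contraction (duration `tau_c`, default 0.2 s): `s = (1 − cos(π u / tau_c)) / 2`
* relaxation (duration `tau_r`, default 0.3 s): `s = (1 + cos(π (u − tau_c) / tau_r)) / 2`

This shape was chosen because its first and second derivatives are closed
form, so every synthetic video carries exact ground truth: peak velocity
`π/(2 tau_c)` and peak acceleration `π²/(2 tau_c²)` per unit amplitude.
Beat onsets arrive at mean rate `f_beat` (default 1.5 Hz, a typical
spontaneous rate for murine syncytia; intervals jittered with CV 0.1 and
clamped so pulses never overlap), with the first beat half a period in.

Markers sit on the 5 × 6 orthogonal grid used for registration and move
radially toward the grid centroid — the simplest displacement field of a
sheet contracting about its center — with amplitude proportional to their
rest distance from the center; the farthest marker realizes the full
per-syncytium amplitude `A0 × amp_mult × L`, where `L` is a lognormal
draw with CV `between_cv` (default 0.2) shared by all videos of one
syncytium. Tracking noise is additive isotropic Gaussian (default
σ = 0.1 px). What the generator deliberately does *not* emulate: non-radial
strain fields, illumination changes, focus drift, arrhythmic beat-shape
variation, and pixel-to-micron calibration (the assay reports pixels).
Passing tests therefore validate the estimator chain, not robustness to
every feature of real microscopy video.

### Frame rate and differentiation: why 50 Hz and a quartic

The raised-cosine pulse has a *discontinuous* second derivative at
contraction onset — the acceleration jumps to its maximum instantly. The
recovery of that maximum from sampled, noisy displacement is the binding
accuracy constraint of the whole pipeline, and it fixes three defaults
jointly (established by a numerical design study before the pipeline was
frozen, sweeping polynomial order 2–5, window 3–15 samples and frame rates
25–100 Hz):

* **fs = 50 Hz.** At 25 Hz every local-polynomial filter attenuates the
  acceleration peak by ≥ 20%; at 75–100 Hz the second-derivative noise
  gain (∝ fs²) inflates the beat-wise maximum by tens of percent at
  σ = 0.1 px. 50 Hz balances the two (median acceleration error ≈ 5%).
* **Savitzky–Golay order 4, window 7 samples (0.14 s).** The quartic's
  second-derivative filter slightly overshoots near the onset
  discontinuity, compensating the smoothing loss; the 7-sample window is
  the narrowest symmetric quartic window. Order 3 over the same window
  attenuates the peak by ~45%; wider windows lose the peak, narrower ones
  are impossible at order 4.

Displacement and velocity are insensitive to these choices (errors well
under 1%); users at other frame rates can retune `window_s` and
`polyorder` (at 25 Hz, `polyorder = 5` tracks the velocity peak to ~2%).
Derivatives at the record edges use the one-sided fit rows of the filter
matrix.

## From trajectories to metrics

Displacement is the scalar Euclidean distance from a reference position —
a single non-negative quantity, matching how maximum contraction
displacement is reported. The default reference is the frame-1 position
(markers are placed on the first frame); the `"baseline"` policy instead
averages the decile of frames nearest diastolic rest, which tolerates
recordings whose later frames drift. A fixed coordinate percentile would
pick the contracted extreme, not rest, for the half of the grid whose
coordinates decrease during contraction, so it is not used.

Beats are local maxima of the smoothed displacement with topographic
prominence above a floor, separated by at least `min_period_s` (0.25 s;
closer peaks merge into the higher one). The floor is
`max(4 × mad(diff(raw)), 5% of the signal range)`: the MAD of first
differences of the *unsmoothed* displacement is a noise scale that already
carries the √2 of a difference (a prominence compares two noisy values),
and becomes slope-dominated — hence amplitude-proportional — for beating
signals; the range term covers noiseless signals, whose `mad(diff)` is
exactly zero when the tissue rests most of the time. At the default noise
level a quiescent marker produces zero beats in ≈ 95–98% of recordings.
Onset and end of each beat are the displacement minima flanking the peak;
beats truncated by the record edge are discarded.

Per beat, `D` is the smoothed displacement rise onset→peak, and `V` and
`Acc` are the maxima of the first and second derivatives over that
contraction phase only (the wording "contraction velocity/acceleration"
excludes relaxation; whether the original analysis used the phase maximum
or the onset value is unknowable from the text, and the maximum is this
package's documented choice). Aggregation is unweighted means up the
hierarchy: beats → marker → video → syncytium over the 27–39 min window.
The syncytium (n = 20 per arm) is the experimental unit for all
statistics; markers and beats are never pooled across syncytia.

## Tracking

`track_spot()` re-implements template tracking as used for marker
registration: a static template cut from frame 1 (no template update —
20 s recordings under constant illumination; drift-free by construction),
normalized cross-correlation over a ±10 px search window around the
previous position, and 3-point parabolic subpixel refinement independently
in x and y (bias ≤ 0.05 px for Gaussian spots). Frames whose peak
correlation falls below 0.2 hold the previous position and are flagged;
a trajectory with > 20% lost frames is invalid, and a video with > 50%
invalid markers fails. On noise-free rendered stacks the tracker is
accurate to ~0.002 px RMS; at peak-signal SNR ≈ 10 (Poisson), ~0.12 px.

## Statistics

`one_way_anova()` is the textbook fixed-effects decomposition;
`lsd_pairwise()` computes every pairwise difference with the half-width
`t(0.975, df_within) √(MS_within (1/n_i + 1/n_j))` from the pooled error
variance. LSD is deliberately unadjusted for multiplicity — that is the
method being modelled — and the report says so rather than silently
"improving" it. Significance is decided by CI exclusion of zero (the
"nonoverlapping bars" convention); the t-based p value is also reported.
Whether the original analysis averaged the five acquisitions per syncytium
before testing is not stated; averaging is this package's documented
choice, consistent with treating the syncytium as the unit.

## Condition effects and the calibrated patterns

The four arms act multiplicatively on amplitude (`amp_mult`), on both
phase durations (`tau_mult`), and on beat rate. The defaults
(ISO 1.04 / 0.80, EMF 0.96 / 1.10, ISO+EMF 0.75 / 1.15, between-CV 0.2)
are a *calibration*, chosen by power analysis so the synthetic study
reproduces the qualitative outcome being modelled: at n = 20 and CV 0.2
the LSD significance threshold is ≈ 12.6% of the control mean, so
displacement effects within ±6% stay reliably nonsignificant while the
tau shortening amplifies acceleration (∝ amp/tau²: ISO ≈ 1.6× control)
far beyond it. The combined arm's amplitude suppression (0.75) makes its
displacement deficit detectable. A majority of independently seeded study
replicates then shows: displacement — ISO ns, EMF ns, ISO+EMF
significantly down (vs both CTRL and ISO); acceleration — ISO up*, EMF
down*, ISO+EMF down*. Verdicts are majority votes over 20 seeds with the
split reported, to avoid enshrining one lucky seed.

## Bioreactor dosimetry

The field model is a coaxial pair of air-cored solenoids in series, each
modelled as one circular loop per turn (midpoint placement along the
winding; field by the complete-elliptic-integral closed form, which
matches a 2880-segment Biot–Savart quadrature to machine precision).
The real coil dimensions are not published, so the default geometry is an
explicit calibrated surrogate: R = 50 mm, winding length 50 mm, 30 mm gap,
699 turns per coil, solved so that the printed 0→319 mA ramp yields
≈ 2.83 mT at the culture midplane — the field implied by the printed peak
energy density `u = B²/2μ0 ≈ 3.18 J/m³` and consistent with "circa 3 mT".
The radius, comparable to the coil separation, keeps the radial profile
flat to ≈ 1.2% over the central 30% of the mapped span (the
quasihomogeneity region where the wells sit); transverse components vanish
at the midplane by symmetry. The current pulse is trapezoidal: 1.36 ms
rise (printed), symmetric fall (assumed), plateau filling half the
13.33 ms period (assumed); the induced azimuthal field at dish radius r is
`E = (r/2) dB/dt`, ≈ 18.2 mV/m at the edge of a 35 mm dish during the
ramp. Induced currents and forces inside cells, and thermal effects, are
out of scope.

## Immunofluorescence

The fluorescence module mirrors ImageJ-style quantification on the 0–256
arbitrary-unit scale: Otsu global threshold (a percentile threshold is the
fallback), connected components, an area filter, and the per-cell *mean*
intensity (not integrated — the readout is a level, not a mass). Whether
the original cells were outlined manually or automatically is not stated;
automatic segmentation is the documented choice here. The synthetic
generator places non-overlapping elliptical cells with a smooth dome
profile over a noisy background and records each cell's rendered mean as
ground truth; segmentation recovers counts exactly and means within 2%
when cells are separated. Per-cell intensities are normalized by the
control mean (fold change with a t-based 95% CI) and fed to the same
ANOVA/LSD machinery (ISO 1.3×, EMF 0.75×, ISO+EMF 0.85×, 15% cell SD,
n = 20 cells — large effects, so all three contrasts are significant in
nearly every seed). Fire-LUT pseudocolor is display-only and does not
touch quantification.

## Numerical and degenerate-input conventions

* Pixel coordinates are 1-based with origin at the top-left pixel center;
  x runs along columns, y down rows. All lengths stay in pixels.
* Identical seeds give bit-identical trajectory tables and datasets.
* A zero-amplitude syncytium is valid input everywhere and reports zero
  beats; a marker coincident with the contraction center simply does not
  move. Degenerate beat segments (onset = peak) yield zero metrics with a
  warning. Groups with zero within-variance give p ∈ {0, 1} with a
  warning. Field evaluation within 1 µm of the wire is refused.
* Problem sizes used by the shipped checks: 20-second videos at 50 Hz
  (100 Hz for the noise-free derivative check), 30 markers, 4 × 20
  syncytia × 5 videos per study replicate, 20 replicates for the pattern
  verdicts, 2,000 replicates for the type-I calibration, 50 syncytia for
  parameter recovery.

## Known limitations

The waveform is stereotyped (no beat-to-beat shape variability or
alternans); the displacement field is purely radial; tracking assumes
near-constant illumination and no large inter-frame jumps; the acceleration
estimate is bias-corrected only implicitly through the filter design and
remains ~5% low on noiseless data; the bioreactor geometry is a surrogate
calibrated to printed exposure figures, not a measured coil; and AVI
ingestion is not provided (stacks are multi-page 16-bit TIFF).

```{r}
library(cardiokin)

# one synthetic video, analyzed end to end
grid <- place_marker_grid(640, 480)
ts <- synth_trajectories(condition_params("ISO", amp_mult = 1.04,
                                          tau_mult = 0.8),
                         beat_waveform_params(), grid, seed = 1)
records <- analyze_trajectories(ts, fs = 50)
summarize_video(records)

# a full four-arm study and its statistics
summaries <- simulate_study_summaries(study_design(), seed = 1)
fits <- study_stats(summaries)
fits$Acc_mean$pattern
autoplot(fits$Acc_mean$fit)

# bioreactor dosimetry
field_report()
```
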