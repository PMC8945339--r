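---
title: "Measuring cardiomyocyte shortening and calcium transients with myokinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cardiomyocyte shortening and calcium transients with myokinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myokinet)
```

## The measurement problem

A field-paced adult ventricular myocyte contracts along its long axis: both
tails move toward the cell's central region, which stays fixed. Two
synchronized signals describe each beat — the mechanical displacement of the
tails (bright-field video) and the cytosolic Ca²⁺ transient reported by a
fluorescent indicator (wide-field time-lapse). `myokinet` turns a multi-page
TIFF plus a handful of user-drawn ROIs (two tails, the long axis, a signal
and a background rectangle) into per-beat kinematic and transient metrics.

The default acquisition regime the package is designed around — and the one
its synthetic generator emulates — is 200 frames at 40 fps (25 ms exposure,
5 s record) with 1 Hz pacing, i.e. five beats per record. All spatial
quantities are in pixels; converting to micrometres is deliberately left to
the user, since magnification varies between rigs and every derived ratio
(fraction shortening) is dimensionless anyway.

## Tail tracking

The tracker is frame-0 template matching. The tail ROI's pixels in the first
frame form the template; for every frame the normalized cross-correlation
(NCC) against all integer shifts within a search radius (default 12 px) is
computed — via FFT cross-products and integral-image window sums, so the
cost is independent of the search radius — and the integer peak is refined
by a 3-point parabolic fit per axis. The resulting 2-D shift is projected
onto the unit vector of the user-drawn cell axis, oriented from the tail's
nearest axis endpoint toward the far one, so positive displacement always
means "toward the cell center" regardless of which tail is tracked.

NCC is invariant to affine intensity transforms, which makes the tracker
robust to illumination drift and to any intensity normalisation applied by
the storage path. Degenerate inputs fail loudly: a zero-variance template is
rejected, and if more than 20 % of frames correlate below 0.5 the track is
declared failed rather than silently returning noise.

Velocity and acceleration are central differences of the displacement trace
(one-sided at the record ends). A Savitzky–Golay filter (window 5, order 2)
can be applied before differentiation but is off by default: at 40 fps a
beat's upstroke spans only a few frames and smoothing visibly depresses peak
speeds, so it must be an explicit, logged choice.

Force (px/s²), contractility (px/s) and contraction energy (px²/s²) are
defined operationally as beat means of the per-beat peak |acceleration|,
peak speed and peak squared speed of each tail; the total force sums the two
tails while contractility and energy average them. These peak-based
estimators are this package's own definitions of the classical kinematic
read-outs — the quantities and their units follow the field's convention,
but no canonical formula exists, so the choice is documented here rather
than buried in code.

## Beat segmentation

When the pacing frequency is known, beats are fixed windows of one pacing
period starting at *t* = 0 — the experimenter's stimulator is a better clock
than any detector. Without pacing, beats are detected as peaks of
|displacement| above half the global maximum, thinned to a minimum
separation of 0.4 × the median inter-peak interval, with windows at the
midpoints between peaks. A trace whose maximum does not exceed three scaled
MADs of the displacement distribution raises "no contraction detected".

## Fluorescence extraction and detrending

Per frame, the raw fluorescence is the mean over the signal ROI minus the
mean over the background ROI (zero if absent). The baseline divisor f₀ is
the mean of the dimmest tenth of frames, so a resting cell sits at f/f₀ ≈ 1
independent of dye loading and camera gain. Detrending fits a least-squares
polynomial (order 1 by default) against time, subtracts it, and adds the
pre-detrend global mean back, preserving the f/f₀ ≈ 1 baseline semantics.

## Transient metrology

The transient train is treated as a bi-level waveform. State levels are
first estimated by the histogram-mode method: a 100-bin histogram over the
data range, split at the range midpoint; each state is the center of the
most populated bin in its half (ties to the lower bin). Reference levels sit
at 10/50/90 % of the state span (configurable).

Two practical refinements, both motivated by the fact that a transient train
— unlike the square pulses this style of metrology was designed for — dwells
only at baseline:

* **Cohort-median level refinement.** The upper-half histogram mode
  systematically underestimates the high state of spike-like waveforms
  (briefly-visited peaks populate few bins). After a first detection pass,
  the reference levels are re-anchored at the cohort medians of the
  per-transient peaks and pre-rise minima and the crossings recomputed. For
  waveforms that do dwell at both levels the refined anchors coincide with
  the histogram modes, so square and trapezoid test waveforms are measured
  identically either way.
* **Hysteresis edge pairing with isotonic limbs.** A rising edge requires
  travel from below the lowest reference level to above a 35 %-of-span
  trigger; a falling edge must return below the arm level. This prevents
  sample noise around a single threshold from fabricating transients, while
  still detecting aberrant low-amplitude beats — which must be *detected* to
  be *flagged* as outliers. Each limb is then projected onto its isotonic
  (monotone) regression before reference levels are crossed by linear
  interpolation. The projection is the identity on noiseless monotone data,
  so analytic waveforms (trapezoids, exponentials) are measured exactly; on
  noisy slow decays it removes the early bias of first-crossing detection.

Per transient, the beat onset is the minimum of a lightly smoothed
(3-point) trace in the window before the rise — or the latest pacing time,
if pacing is supplied. τ-to-peak values count from onset to the rising
crossings; τ-of-decay values from the peak sample to the falling crossings;
`amplitude_span` is peak minus onset value. Reading the onset from the
*smoothed* minimum matters twice over: a raw minimum is biased low by noise,
and any averaging window that extends past the anchor is poisoned by the
upstroke, which can be only 2–3 frames wide at 40 fps.

A reference level a transient's peak never reaches yields an `NA` crossing
(a half-amplitude beat has no 90 % crossing); `incomplete` is reserved for
transients cut off by the record's end, which are excluded from all
statistics. Outliers are flagged at median ± 3 scaled MADs (×1.4826) on the
amplitude span or the 90→10 % fall duration, computed over complete
transients; with fewer than three complete transients no screening is
attempted. F_max is the mean amplitude span over retained transients; every
metric is reported as mean ± SEM with the full beat-to-beat table preserved.

## The synthetic generator and what it does (not) show

The generator is first-class, tested code. Transients are double-exponential
pulses — chosen over an alpha function because rise and decay are
independently tunable and the peak time is closed-form — normalised to peak
at the requested amplitude, summed over 1 Hz onsets, plus optional linear
drift and additive Gaussian noise. Default time constants (rise 0.05 s,
decay 0.25 s) and amplitude (1 f/f₀ unit over a baseline of 1) are typical
of Fluo-4 transients in adult murine myocytes at this frame rate; the
default noise level (σ = 0.02) corresponds to a clean wide-field recording.

Videos render a striated rod (sinusoidal texture plus a soft envelope that
breaks the texture's periodicity) on a dark background. Per frame, each half
of the rod is warped toward the fixed center by a displacement field that is
zero over the central 15 % of the half-length, ramps linearly, and
saturates at the full tail shift over the outer 30 % — so the tail ends
move rigidly where the tracker reads them, matching the "moving tails,
fixed center" physics. The shift waveform reuses the transient pulse shape,
scaled so the per-beat maxima of both tails sum to the target fraction
shortening. Rendering is by analytic inverse mapping (the resting intensity
function is evaluated at inverse-warped coordinates), so no resampling
blur is introduced.

Ground truth deserves a precise definition. At 1 Hz pacing with slow decay
(τ ≈ 0.25–0.3 s) the clean waveform never returns to the resting baseline
between beats — the residual is 3–5 % of the amplitude. The ideal resting
baseline is therefore *unobservable by any analyser*, and τ values
referenced to it are unrecoverable in principle. The exported truth is
instead what an ideal instrument would measure on the noiseless, driftless
waveform: per-beat anchors (pre-onset minimum, per-beat peak) and global
median reference levels, computed on a 50× oversampled grid directly from
the generating equations, independent of the analysis code. Closed-form
single-pulse crossing offsets are exported alongside.

Passing recovery tests on these synthetics demonstrates correct geometry,
timing and noise behaviour of the pipeline. It does **not** demonstrate
robustness to what the generator omits: photon (Poisson) noise, motion blur
within the 25 ms exposure, focus drift, neighbouring cells entering an ROI,
or pacing failures. Those failure modes are exactly why the tracker reports
per-frame correlation quality and the metrology flags rather than silently
drops aberrant beats.

## Numerical choices and conventions

* Coordinates are 0-based `(row, col)`, origin top-left; rectangles are
  half-open, so `height × width` counts pixels exactly. Frame *k* (1-based)
  is at *t* = (*k* − 1) · Δt; no exposure-midpoint correction.
* Crossing times are linear interpolations between bracketing samples — no
  model fitting anywhere in the measurement path.
* Sub-pixel refinement clamps the parabolic offset to ±0.5 px and falls
  back to the integer peak when the 3-point stencil is not concave or the
  peak sits on the search-window edge.
* Histogram mode ties resolve to the lower bin; a single-valued trace is a
  "no bi-level structure" error, not a result.
* MAD uses the 1.4826 normal-consistency factor (R's default). With MAD = 0
  (identical beats) nothing is flagged unless a value differs from the
  median at all.
* `write_stack` normalises intensities into [0, 1] (pure scaling for
  nonnegative data). Absolute intensity units are not preserved — ratio
  quantities (f/f₀, NCC) are unaffected.
* Batch runs are deterministic: reanalysing the same config and seeds
  yields byte-identical CSVs.

## Problem sizes

The test suite and the acceptance script use the package's native regime —
200-frame, 40 fps, 1 Hz records; videos of 96 × 160 px with L₀ = 100 px;
3–5 seeds per condition; grids of τ ∈ {0.1, 0.2, 0.3} s × amplitude ∈
{0.5, 1.5}; 1000 replicates for the Welch type-I check. These sizes give
sub-minute turnaround per module while leaving every recovery margin
comfortably resolvable (tracking errors are ~0.05 px against tolerances of
0.1–0.15 px; τ recovery errors ≤ ~7 % against a 10 % band).

## Known limitations

* Tracking assumes the tail stays within the search radius (±12 px) of its
  frame-0 position and that the template remains representative; gross cell
  movement or focus loss will trip the correlation-quality guard rather
  than be corrected.
* The axis is a straight line: strongly bent cells violate the projection
  geometry.
* τ-to-peak at 40 fps resolves the upstroke with only 2–3 samples; its SEM
  is dominated by sampling, not biology. Higher frame rates help the rise
  metrics far more than the decay metrics.
* AVI containers are not read; export image stacks as multi-page TIFF.
* Fura-2-style ratiometric recordings and spatial Ca²⁺ wave analysis are
  out of scope.
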