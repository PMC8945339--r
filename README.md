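# myokinet

Contraction kinematics and calcium-transient metrology for isolated adult
cardiomyocytes, from microscopy video to per-beat statistics.

Freshly isolated adult ventricular myocytes are rod-shaped cells that, when
field-paced (typically at 1 Hz), shorten by pulling both tails toward a
fixed central region. Two synchronized read-outs characterise their
excitation–contraction coupling: the mechanical shortening seen in
bright-field video, and the cytosolic Ca²⁺ transient reported by a
fluorescent dye (e.g. Fluo-4) in wide-field time-lapse stacks. `myokinet`
quantifies both from ordinary multi-page TIFF recordings plus user-drawn
regions of interest — no specialised acquisition hardware, no sarcomere
regularity requirement, and per-beat (not merged-beat) statistics
throughout.

## What it computes

**Shortening / kinematics.** Each tail ROI is tracked by frame-0 template
matching: normalized cross-correlation over a ±12 px search window, 3-point
parabolic sub-pixel refinement, and projection of the 2-D shift onto the
cell's long axis. With the uncontracted length L₀ (px) measured from the
axis ROI and MD₁, MD₂ the mean-over-beats maximum tail displacements (px),

    FS (%) = 100 · (MD₁ + MD₂) / (L₀ / 2)

Per beat and per tail, the peak speed |ẋ| (px/s), peak acceleration |ẍ|
(px/s²) and peak squared speed (px²/s²) give the tail's contractility,
force and contraction energy; the total force sums the tails, contractility
and energy average them.

**Calcium transients.** The trace f/f₀ is the background-subtracted mean
ROI fluorescence normalised by the mean of its dimmest decile of frames,
optionally detrended (least-squares, mean-preserving). Bi-level waveform
metrology in the style of IEEE Std 181 then locates each transient: state
levels by the histogram-mode method (with a cohort-median refinement for
spike-like trains), 10/50/90 % reference-level crossings by linear
interpolation on isotonic-projected limbs, per-beat τ-to-peak and τ-of-decay
(e.g. `tau_fall_10`, the transient's "lifetime" from peak to the
10 % crossing), amplitude span, a median ± 3·MAD outlier screen, and the
transient amplitude F_max as the mean peak-to-baseline span over retained
beats. Incomplete final transitions are flagged and excluded.

**Statistics.** Welch's t-test and OLS regression with Spearman ρ (mean ±
SEM reporting), plus a batch driver for many cells and two-condition
comparisons.

**Synthetic ground truth.** A seeded generator renders paced-cell videos
(striated rod, tails warped toward a fixed center, target FS) and transient
trains (double-exponential pulses, drift, noise) together with the values an
ideal instrument would measure, so the entire pipeline is testable without
microscope data.

## Worked example

```r
library(myokinet)

# a 200-frame, 40 fps, 1 Hz-paced synthetic cell, target FS 8%
sim <- simulate_video(video_sim_spec(fs_percent = 8, seed = 3))
m   <- analyze_shortening(sim$stack, sim$rois, pacing_hz = 1)
m
#> <kinematics_metrics> 5 beat(s)
#>   MD1 1.981 px  MD2 1.989 px  L0 100.0 px
#>   fraction shortening 7.94 %
#>   force 1683.74 px/s^2  contractility 42.67 px/s  energy 1878.40 px^2/s^2
```

The two tails each peak near 1.99 px per beat; with L₀ = 100 px the FS
formula gives 100·(1.981+1.989)/50 ≈ 7.94 %, within 1 % of the generator's
ground truth (7.94 % realised for a target of 8 %). `tidy(m)` returns the
per-beat table, `glance(m)` the one-row cell summary, `autoplot()` the
displacement traces.

```r
st  <- simulate_trace(trace_sim_spec(seed = 2))       # 5 transients, 1 Hz
f   <- simulate_fluorescence_stack(st$trace)
res <- analyze_calcium(f$stack, f$rois, pacing_hz = 1)
res$summary
#> <transient_summary> 5 transient(s): 5 retained, 0 outlier(s), 0 incomplete
#>   F_max (mean peak-to-baseline span): 0.9638
#>   tau_to_peak_10   0.006527 +/- 0.00162 (n=5)
#>   tau_fall_10        0.5345 +/- 0.0445 (n=5)
#>   ...
```

`F_max ≈ 0.96` recovers the injected unit amplitude; `tau_fall_10 ≈ 0.53 s`
matches the clean-waveform truth for a 0.25 s decay constant (≈ 0.56 s)
within a few percent. `autoplot(res$trace, transients = res$metrics)` draws
the trace with rise/fall crossing markers; `plot_beat_variability()` shows
the stacked per-beat τ segments.

A thin command-line front end lives in `inst/cli/myokinet.R`
(`shorten`, `calcium`, `simulate`, `report` subcommands); `run_batch()`
processes a YAML/JSON config of many cells into pooled group tables and
Welch comparisons.

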