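#' Specification of a synthetic calcium-transient trace
#'
#' Defaults emulate the acquisition regime of a typical paced-myocyte
#' recording: 40 fps, 200 frames (5 s), 1 Hz field pacing. The transient is
#' a double-exponential pulse (fast rise, slower decay), normalised so its
#' peak equals `amplitude`; rise and decay time constants default to values
#' typical of Fluo-4 transients in adult murine myocytes (upstroke tens of
#' milliseconds, decay a few hundred).
#'
#' @param fps frames per second.
#' @param n_frames number of frames.
#' @param pacing_hz pacing frequency (beat onsets at `k / pacing_hz`).
#' @param amplitude pulse peak above baseline, in f/f0 units. A vector is
#'   recycled across beats, so e.g. a single aberrant half-amplitude beat can
#'   be injected.
#' @param tau_rise,tau_decay rise and decay time constants, seconds
#'   (`tau_rise < tau_decay`).
#' @param baseline resting f/f0 level.
#' @param drift_slope linear baseline drift, f/f0 units per second.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer RNG seed; the generator never touches global RNG
#'   state.
#'
#' @return A list of class `trace_sim_spec`.
#' @export
trace_sim_spec <- function(fps = 40, n_frames = 200, pacing_hz = 1,
                           amplitude = 1.0, tau_rise = 0.05, tau_decay = 0.25,
                           baseline = 1.0, drift_slope = 0, noise_sd = 0.02,
                           seed = 1L) {
  spec <- list(fps = fps, n_frames = n_frames, pacing_hz = pacing_hz,
               amplitude = amplitude, tau_rise = tau_rise,
               tau_decay = tau_decay, baseline = baseline,
               drift_slope = drift_slope, noise_sd = noise_sd,
               seed = as.integer(seed))
  if (tau_rise >= tau_decay) abort_input("tau_rise must be smaller than tau_decay")
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  if (any(amplitude <= 0)) abort_input("amplitude must be > 0")
  if (n_frames / fps < 1 / pacing_hz)
    abort_input("record must cover at least one full beat")
  structure(spec, class = "trace_sim_spec")
}

# normalised double-exponential pulse shape: 0 at onset, peak 1 at t_peak
pulse_shape <- function(dt_s, tau_rise, tau_decay) {
  tpk <- pulse_peak_time(tau_rise, tau_decay)
  norm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- (exp(-dt_s / tau_decay) - exp(-dt_s / tau_rise)) / norm
  out[dt_s < 0] <- 0
  out
}

# closed-form argmax of the double exponential
pulse_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# time (after onset) at which the normalised pulse crosses fraction p,
# on the rising (before peak) or falling (after peak) limb; by bisection on
# the analytic shape, independent of the trace analysis code
pulse_crossing_time <- function(p, tau_rise, tau_decay,
                                limb = c("rise", "fall")) {
  limb <- match.arg(limb)
  tpk <- pulse_peak_time(tau_rise, tau_decay)
  f <- function(x) pulse_shape(x, tau_rise, tau_decay) - p
  if (limb == "rise") {
    stats::uniroot(f, c(0, tpk), tol = 1e-12)$root
  } else {
    upper <- tpk + tau_decay * (log(1 / p) + 10)
    stats::uniroot(f, c(tpk, upper), tol = 1e-12)$root
  }
}

#' Simulate a calcium-transient train
#'
#' Builds `baseline + sum of pulses + drift + noise` on the frame grid. The
#' pulse train places one double-exponential transient at each pacing onset
#' `o_k = k / pacing_hz` inside the record. The returned ground truth holds
#' the generating parameters and analytic per-beat event times (onset, peak,
#' and reference-level crossing offsets computed from the closed-form pulse
#' shape), so recovery tests can compare against truth that is independent
#' of the analysis code.
#'
#' @param spec a [trace_sim_spec()].
#' @return A list with `trace` (a `fluorescence_trace` tibble: `time_s`,
#'   `f_over_f0`) and `truth` (list: per-beat tibble `beats`, closed-form
#'   single-pulse crossing offsets `single_pulse_rise_s` /
#'   `single_pulse_fall_s`, the clean waveform, and the generating spec).
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  dt <- 1 / spec$fps
  t <- (seq_len(spec$n_frames) - 1) * dt
  onsets <- seq(0, t[length(t)], by = 1 / spec$pacing_hz)
  amps <- rep_len(spec$amplitude, length(onsets))
  clean <- rep(spec$baseline, length(t))
  for (k in seq_along(onsets))
    clean <- clean + amps[k] * pulse_shape(t - onsets[k], spec$tau_rise, spec$tau_decay)
  clean <- clean + spec$drift_slope * t
  noise <- if (spec$noise_sd > 0)
    withr::with_seed(spec$seed, stats::rnorm(length(t), 0, spec$noise_sd))
  else rep(0, length(t))
  y <- clean + noise

  tpk <- pulse_peak_time(spec$tau_rise, spec$tau_decay)
  refs <- c(0.10, 0.50, 0.90)
  rise_off <- vapply(refs, pulse_crossing_time, numeric(1L),
                     tau_rise = spec$tau_rise, tau_decay = spec$tau_decay,
                     limb = "rise")
  fall_off <- vapply(refs, pulse_crossing_time, numeric(1L),
                     tau_rise = spec$tau_rise, tau_decay = spec$tau_decay,
                     limb = "fall")
  truth <- list(
    beats = trace_truth_beats(spec, onsets, refs),
    single_pulse_rise_s = stats::setNames(rise_off, paste0("r", refs * 100)),
    single_pulse_fall_s = stats::setNames(fall_off - tpk, paste0("f", refs * 100)),
    clean = clean, spec = spec)

  trace <- new_fluorescence_trace(t, y, f0_value = spec$baseline,
                                  detrended = FALSE,
                                  provenance = "synthetic trace")
  list(trace = trace, truth = truth)
}

# Per-beat ground-truth event times of the clean (noiseless, driftless)
# pulse train, evaluated on a dense time grid. At physiological pacing the
# waveform need not return to the resting baseline between beats, so no
# analyser -- however good -- can reference the ideal baseline; ground truth
# therefore anchors each beat at the clean waveform's pre-onset minimum and
# its own peak, i.e. at what an ideal instrument measuring the noiseless
# signal would report. Independent of the analysis code.
trace_truth_beats <- function(spec, onsets, refs) {
  period <- 1 / spec$pacing_hz
  t_end <- (spec$n_frames - 1) / spec$fps
  dense_dt <- 1 / spec$fps / 50
  tg <- seq(0, t_end, by = dense_dt)
  amps <- rep_len(spec$amplitude, length(onsets))
  yc <- rep(spec$baseline, length(tg))
  for (k in seq_along(onsets))
    yc <- yc + amps[k] * pulse_shape(tg - onsets[k], spec$tau_rise, spec$tau_decay)

  cross_up <- function(idx, level) {
    hit <- idx[which(yc[idx] < level & yc[idx + 1L] >= level)[1L]]
    if (is.na(hit)) return(NA_real_)
    tg[hit] + dense_dt * (level - yc[hit]) / (yc[hit + 1L] - yc[hit])
  }
  cross_down <- function(idx, level) {
    hit <- idx[which(yc[idx] >= level & yc[idx + 1L] < level)[1L]]
    if (is.na(hit)) return(NA_real_)
    tg[hit] + dense_dt * (level - yc[hit]) / (yc[hit + 1L] - yc[hit])
  }

  # clean per-beat anchors; the reference levels are global (cohort medians),
  # matching the global-state-level semantics of the measurand
  base_v <- vapply(onsets, function(o) yc[which.min(abs(tg - o))], numeric(1L))
  pk_i <- vapply(seq_along(onsets), function(k) {
    win <- which(tg >= onsets[k] & tg < min(onsets[k] + period, t_end + dense_dt))
    win[which.max(yc[win])]
  }, integer(1L))
  low <- stats::median(base_v)
  high <- stats::median(yc[pk_i])

  purrr::map_dfr(seq_along(onsets), function(k) {
    o <- onsets[k]
    pk_t <- tg[pk_i[k]]; pk_v <- yc[pk_i[k]]
    row <- tibble::tibble(beat = k, onset_s = o, onset_value = base_v[k],
                          peak_s = pk_t, peak_value = pk_v,
                          amplitude = amps[k],
                          amplitude_span = pk_v - base_v[k])
    rise_idx <- which(tg >= o & tg < pk_t)
    fall_idx <- which(tg >= pk_t & tg < min(o + period, t_end))
    for (p in refs) {
      lev <- low + p * (high - low)
      tr <- cross_up(rise_idx, lev)
      tf <- cross_down(fall_idx, lev)
      row[[sprintf("tau_to_peak_%d", round(p * 100))]] <- tr - o
      row[[sprintf("tau_fall_%d", round(p * 100))]] <- tf - pk_t
    }
    row
  })
}

#' Specification of a synthetic contraction video
#'
#' Renders a rod-shaped cell with sinusoidal striation texture on a dark
#' background; per frame the two halves of the rod are warped toward the
#' fixed center following a double-exponential displacement pulse train. The
#' axial displacement profile is zero over the central 15% of each
#' half-length, ramps linearly, and saturates at the full tail shift over the
#' outer 30%, so the tail ends move rigidly (where the tracker reads them)
#' while the center stays fixed.
#'
#' @param frame_h,frame_w frame size in px.
#' @param l0_px resting cell length, px.
#' @param width_px cell width, px.
#' @param angle_deg orientation of the long axis (0 = horizontal).
#' @param fs_percent target fraction shortening, percent (0 <= FS < 30).
#' @param fps,n_frames,pacing_hz acquisition regime (defaults 40 fps, 200
#'   frames, 1 Hz).
#' @param tau_rise,tau_decay displacement pulse time constants, seconds.
#' @param striation_period_px sarcomere striation period of the texture.
#' @param noise_sd additive Gaussian pixel noise (intensity units; the cell
#'   is rendered at amplitude ~0.8 over a 0.08 background).
#' @param seed integer RNG seed.
#' @return A list of class `video_sim_spec`.
#' @export
video_sim_spec <- function(frame_h = 96, frame_w = 160, l0_px = 100,
                           width_px = 18, angle_deg = 0, fs_percent = 5,
                           fps = 40, n_frames = 200, pacing_hz = 1,
                           tau_rise = 0.04, tau_decay = 0.12,
                           striation_period_px = 6, noise_sd = 0.01,
                           seed = 1L) {
  if (fs_percent < 0 || fs_percent >= 30)
    abort_input("target fraction shortening must be in [0, 30)%")
  if (tau_rise >= tau_decay) abort_input("tau_rise must be smaller than tau_decay")
  spec <- list(frame_h = frame_h, frame_w = frame_w, l0_px = l0_px,
               width_px = width_px, angle_deg = angle_deg,
               fs_percent = fs_percent, fps = fps, n_frames = n_frames,
               pacing_hz = pacing_hz, tau_rise = tau_rise,
               tau_decay = tau_decay,
               striation_period_px = striation_period_px,
               noise_sd = noise_sd, seed = as.integer(seed))
  structure(spec, class = "video_sim_spec")
}

# resting intensity of the cell in cell coordinates (xi along axis, eta across)
cell_intensity <- function(xi, eta, spec) {
  soft <- function(x, s = 1.5) 1 / (1 + exp(-x / s))
  rod <- soft(spec$l0_px / 2 - abs(xi)) * soft(spec$width_px / 2 - abs(eta))
  striae <- 0.75 + 0.25 * sin(2 * pi * xi / spec$striation_period_px)
  envelope <- 0.85 + 0.15 * cos(pi * xi / spec$l0_px)
  0.08 + 0.8 * rod * striae * envelope
}

# axial shift fraction: 0 at center, ramp, full shift over the outer tail
warp_profile <- function(xi_norm) {
  pmin(pmax((abs(xi_norm) - 0.15) / (0.70 - 0.15), 0), 1)
}

#' Simulate a contraction video with ground truth
#'
#' @param spec a [video_sim_spec()].
#' @return A list with `stack` (a [frame_stack()]), `rois` (two tail
#'   rectangles + the axis line), and `truth` (per-frame tail shift,
#'   per-beat maximum displacement, target and realised FS, peak speed and
#'   acceleration of the tail shift waveform).
#' @export
simulate_video <- function(spec) {
  stopifnot(inherits(spec, "video_sim_spec"))
  dt <- 1 / spec$fps
  t <- (seq_len(spec$n_frames) - 1) * dt
  half <- spec$l0_px / 2

  # per-tail peak shift so that MD1 + MD2 = FS * (L0/2) / 100
  d_max <- spec$fs_percent * half / 100 / 2
  onsets <- seq(0, t[length(t)], by = 1 / spec$pacing_hz)
  d_t <- rep(0, length(t))
  for (o in onsets)
    d_t <- d_t + d_max * pulse_shape(t - o, spec$tau_rise, spec$tau_decay)

  theta <- spec$angle_deg * pi / 180
  r0 <- (spec$frame_h - 1) / 2
  c0 <- (spec$frame_w - 1) / 2
  rows <- seq_len(spec$frame_h) - 1
  cols <- seq_len(spec$frame_w) - 1
  rr <- matrix(rows, spec$frame_h, spec$frame_w) - r0
  cc <- matrix(cols, spec$frame_h, spec$frame_w, byrow = TRUE) - c0
  xi <- cc * cos(theta) + rr * sin(theta)
  eta <- -cc * sin(theta) + rr * cos(theta)

  margin <- 25
  grid <- seq(-(half + margin), half + margin, by = 0.25)
  gprof <- warp_profile(grid / half)

  noise <- if (spec$noise_sd > 0)
    withr::with_seed(spec$seed,
      stats::rnorm(spec$n_frames * spec$frame_h * spec$frame_w, 0, spec$noise_sd))
  else 0
  noise <- array(noise, dim = c(spec$n_frames, spec$frame_h, spec$frame_w))

  px <- array(0, dim = c(spec$n_frames, spec$frame_h, spec$frame_w))
  for (k in seq_along(t)) {
    mapped <- grid - sign(grid) * d_t[k] * gprof  # rest -> current position
    xi0 <- stats::approx(mapped, grid, xout = as.vector(xi), rule = 2)$y
    frame <- cell_intensity(xi0, as.vector(eta), spec)
    px[k, , ] <- matrix(frame, spec$frame_h, spec$frame_w) + noise[k, , ]
  }
  stack <- frame_stack(px, dt, origin_label = sprintf("synthetic video seed %d", spec$seed))

  rois <- synthetic_video_rois(spec)
  for (roi in rois) validate_roi_bounds(roi, c(spec$frame_h, spec$frame_w))

  per_beat <- vapply(onsets, function(o) {
    in_beat <- t >= o & t < o + 1 / spec$pacing_hz
    max(d_t[in_beat])
  }, numeric(1L))
  v <- finite_diff(d_t, dt)
  a <- finite_diff(v, dt)
  truth <- list(
    tail_shift_px = d_t, per_beat_md_px = per_beat,
    md_mean_px = mean(per_beat),
    fs_percent = 100 * 2 * mean(per_beat) / half,
    fs_target = spec$fs_percent,
    peak_speed_px_s = max(abs(v)), peak_accel_px_s2 = max(abs(a)),
    onsets_s = onsets, spec = spec)
  list(stack = stack, rois = rois, truth = truth)
}

# tail rectangles (bounding boxes covering the rigid tail end incl. the tip
# edge) and the axis line, in frame coordinates
synthetic_video_rois <- function(spec) {
  theta <- spec$angle_deg * pi / 180
  r0 <- (spec$frame_h - 1) / 2
  c0 <- (spec$frame_w - 1) / 2
  half <- spec$l0_px / 2
  to_frame <- function(xi, eta)
    c(r0 + xi * sin(theta) + eta * cos(theta),
      c0 + xi * cos(theta) - eta * sin(theta))
  bbox <- function(xi_lim, eta_lim, label) {
    corners <- rbind(to_frame(xi_lim[1L], eta_lim[1L]),
                     to_frame(xi_lim[1L], eta_lim[2L]),
                     to_frame(xi_lim[2L], eta_lim[1L]),
                     to_frame(xi_lim[2L], eta_lim[2L]))
    row0 <- floor(min(corners[, 1L])); row1 <- ceiling(max(corners[, 1L]))
    col0 <- floor(min(corners[, 2L])); col1 <- ceiling(max(corners[, 2L]))
    roi_spec(label, "tail", rect = c(row0, col0, row1 - row0, col1 - col0))
  }
  eta_lim <- c(-spec$width_px / 2 - 3, spec$width_px / 2 + 3)
  tail1 <- bbox(c(-half - 4, -half + 10), eta_lim, "tail1")
  tail2 <- bbox(c(half - 10, half + 4), eta_lim, "tail2")
  p1 <- to_frame(-half, 0); p2 <- to_frame(half, 0)
  axis <- roi_spec("axis1", "axis", line = rbind(p1, p2))
  list(tail1, tail2, axis)
}

#' Render a fluorescence trace as an image stack
#'
#' Builds a wide-field-style stack in which a bright signal region follows
#' the supplied f/f0 trace on top of a uniform background, so the full
#' stack-to-trace extraction path can be exercised against known per-frame
#' ROI means (returned as ground truth).
#'
#' @param trace a `fluorescence_trace` (e.g. from [simulate_trace()]).
#' @param frame_h,frame_w frame size in px.
#' @param gain intensity units per f/f0 unit in the signal region.
#' @param background_level uniform background intensity.
#' @param noise_sd additive Gaussian pixel noise.
#' @param seed integer RNG seed.
#' @return A list with `stack`, `rois` (one `signal`, one `background`
#'   rectangle) and `truth` (per-frame true signal and background ROI
#'   means).
#' @export
simulate_fluorescence_stack <- function(trace, frame_h = 48, frame_w = 64,
                                        gain = 120, background_level = 30,
                                        noise_sd = 0, seed = 1L) {
  n <- nrow(trace)
  dt <- trace$time_s[2L] - trace$time_s[1L]
  sig_rect <- c(8, 8, 24, 28)
  bg_rect <- c(8, frame_w - 20, 24, 14)
  noise <- if (noise_sd > 0)
    withr::with_seed(seed, stats::rnorm(n * frame_h * frame_w, 0, noise_sd))
  else 0
  px <- array(background_level, dim = c(n, frame_h, frame_w))
  for (k in seq_len(n)) {
    px[k, (sig_rect[1L] + 1L):(sig_rect[1L] + sig_rect[3L]),
       (sig_rect[2L] + 1L):(sig_rect[2L] + sig_rect[4L])] <-
      background_level + gain * trace$f_over_f0[k]
  }
  px <- px + array(noise, dim = dim(px))
  stack <- frame_stack(px, dt, origin_label = "synthetic fluorescence stack")
  rois <- list(roi_spec("signal1", "signal", rect = sig_rect),
               roi_spec("bg1", "background", rect = bg_rect))
  truth <- list(signal_mean = background_level + gain * trace$f_over_f0,
                background_mean = rep(background_level, n))
  list(stack = stack, rois = rois, truth = truth)
}
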