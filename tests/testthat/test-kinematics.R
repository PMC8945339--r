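horizontal_axis <- rbind(c(32, 2), c(32, 62))

test_that("pure integer translation is recovered to within 0.1 px", {
  # patch moves +3 columns (toward the right axis end) after frame 1
  stk <- translated_patch_stack(6, shifts_c = c(0, rep(3, 5)))
  roi <- roi_spec("tail1", "tail", rect = c(26, 26, 12, 12))
  tr <- track_tail(stk, roi, horizontal_axis)
  expect_equal(tr$displacement_px[1], 0)
  expect_true(all(abs(tr$displacement_px[-1] - 3) <= 0.1))
})

test_that("a static stack tracks as identically zero with perfect correlation", {
  stk <- translated_patch_stack(5)
  roi <- roi_spec("tail1", "tail", rect = c(26, 26, 12, 12))
  tr <- track_tail(stk, roi, horizontal_axis)
  expect_equal(tr$displacement_px, rep(0, 5))
  expect_equal(tr$correlation_peak, rep(1, 5), tolerance = 1e-9)
})

test_that("flat templates and decorrelated frames raise tracking errors", {
  px <- array(0.2, dim = c(4, 40, 40))
  stk <- frame_stack(px, 0.025)
  roi <- roi_spec("flat", "tail", rect = c(14, 14, 8, 8))
  expect_error(track_tail(stk, roi, rbind(c(20, 0), c(20, 39))), "flat")

  px <- withr::with_seed(7, array(runif(8 * 48 * 48), dim = c(8, 48, 48)))
  stk <- frame_stack(px, 0.025)
  roi <- roi_spec("noisy", "tail", rect = c(18, 18, 10, 10))
  expect_error(track_tail(stk, roi, rbind(c(24, 0), c(24, 47))),
               "tracking failed")
})

test_that("sub-pixel sinusoidal motion is recovered within 0.15 px", {
  t <- (0:79) * 0.025
  shifts <- 2.5 * sin(2 * pi * 1 * t)
  stk <- subpixel_shift_stack(shifts)
  roi <- roi_spec("tail1", "tail", rect = c(14, 30, 18, 24))
  axis <- rbind(c(23, 90), c(23, 10))
  tr <- track_tail(stk, roi, axis)
  # the ROI sits nearer the low-column axis end, so "toward center" is +col
  expect_true(max(abs(tr$displacement_px - shifts)) < 0.15)
  expect_equal(max(abs(tr$displacement_px)), 2.5, tolerance = 0.15)
})

test_that("pacing segmentation yields fixed windows, peak mode brackets beats", {
  t <- (0:199) * 0.025
  tr <- make_displacement_trace(t, rep(0, 200))
  beats <- beat_segment(tr, pacing_hz = 1)
  expect_equal(nrow(beats), 5L)
  expect_equal(beats$t_start, 0:4)
  expect_equal(beats$t_end, 1:5)

  expect_error(beat_segment(tr), "no contraction")

  # four asymmetric injected beats, no pacing given
  peaks_at <- c(0.6, 1.55, 2.4, 3.5)
  y <- rowSums(vapply(peaks_at, function(p) 2 * exp(-((t - p) / 0.08)^2),
                      numeric(length(t))))
  tr <- make_displacement_trace(t, y)
  beats <- beat_segment(tr)
  expect_equal(nrow(beats), 4L)
  for (i in seq_along(peaks_at))
    expect_true(beats$t_start[i] <= peaks_at[i] && peaks_at[i] < beats$t_end[i])
})

test_that("per-beat maximum displacement averages arithmetically", {
  t <- (0:119) * 0.025
  y <- numeric(120)
  y[t >= 0 & t < 1] <- 2.0 * sin(pi * t[t >= 0 & t < 1])
  y[t >= 1 & t < 2] <- 2.2 * sin(pi * (t[t >= 1 & t < 2] - 1))
  y[t >= 2 & t < 3] <- 1.8 * sin(pi * (t[t >= 2 & t < 3] - 2))
  tr <- make_displacement_trace(t, y)
  beats <- beat_segment(tr, pacing_hz = 1)
  md <- max_displacement(tr, beats)
  expect_equal(md$per_beat$md_px, c(2.0, 2.2, 1.8), tolerance = 1e-3)
  expect_equal(md$md_mean_px, 2.0, tolerance = 1e-3)

  one <- max_displacement(tr, beats[2, ])
  expect_equal(one$md_mean_px, one$per_beat$md_px[1])
})

test_that("fraction shortening follows (MD1+MD2)/(L0/2)", {
  expect_equal(fraction_shortening(2, 3, 100), 10)
  expect_equal(fraction_shortening(0, 0, 80), 0)
  expect_equal(fraction_shortening(1.5, 1.0, 100), 5)
  expect_error(fraction_shortening(1, 1, 0), "positive")
  expect_error(fraction_shortening(-1, 1, 100), ">= 0")
})

test_that("kinematic parameters match closed forms on ramps and sines", {
  t <- (0:39) * 0.025
  ramp <- make_displacement_trace(t, 4 * t)
  beats <- tibble::tibble(beat = 1L, t_start = 0, t_end = 1)
  kin <- kinematic_params(ramp, ramp, beats)
  expect_equal(kin$contractility_px_s, 4, tolerance = 1e-9)
  expect_equal(kin$energy_px2_s2, 16, tolerance = 1e-9)
  # constant speed: interior acceleration identically zero
  expect_equal(kin$force_total_px_s2, 0, tolerance = 1e-9)
  # energy equals squared peak speed for a monotone speed profile
  expect_equal(kin$energy_px2_s2, kin$contractility_px_s^2, tolerance = 1e-9)

  f <- 1; A <- 2
  t <- (0:199) * 0.025
  sine <- make_displacement_trace(t, A * sin(2 * pi * f * t))
  beats <- beat_segment(sine, pacing_hz = 1)
  kin <- kinematic_params(sine, sine, beats)
  expect_equal(kin$contractility_px_s, 2 * pi * f * A, tolerance = 0.02 * 2 * pi * f * A)
  expect_equal(kin$force_total_px_s2, 2 * (2 * pi * f)^2 * A,
               tolerance = 0.02 * 2 * (2 * pi * f)^2 * A)
  # identical tails: total force is twice one tail's force, the averaged
  # parameters equal the single-tail values
  tail1 <- kin$per_beat[kin$per_beat$tail == 1L, ]
  expect_equal(kin$force_total_px_s2, 2 * mean(tail1$peak_accel_px_s2))
  expect_equal(kin$contractility_px_s, mean(tail1$peak_speed_px_s))
})

test_that("full shortening pipeline recovers generator ground truth", {
  sim <- simulate_video(video_sim_spec(fs_percent = 8, seed = 11))
  m <- analyze_shortening(sim$stack, sim$rois, pacing_hz = 1)
  expect_equal(m$FS_percent, sim$truth$fs_percent,
               tolerance = 0.1 * sim$truth$fs_percent)
  expect_equal(m$L0_px, 100)
  expect_equal(m$n_beats, 5L)
  # per-beat MD against the generator's per-beat maxima
  md1 <- m$per_beat$md_px[m$per_beat$tail == 1L]
  expect_true(all(abs(md1 - sim$truth$per_beat_md_px) < 0.15))

  g <- glance(m)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$FS_percent, m$FS_percent)
  expect_true(all(c("beat", "tail", "md_px") %in% names(tidy(m))))
})

test_that("fraction shortening is invariant to spatial rescaling", {
  s1 <- simulate_video(video_sim_spec(fs_percent = 8, seed = 5))
  s2 <- simulate_video(video_sim_spec(fs_percent = 8, seed = 5,
                                      l0_px = 200, width_px = 36,
                                      frame_h = 120, frame_w = 288,
                                      striation_period_px = 12))
  m1 <- analyze_shortening(s1$stack, s1$rois, pacing_hz = 1)
  m2 <- analyze_shortening(s2$stack, s2$rois, pacing_hz = 1)
  expect_equal(m2$FS_percent, m1$FS_percent, tolerance = 0.05 * m1$FS_percent)
})

test_that("time-reversed video mirrors the forward displacement pattern", {
  sim <- simulate_video(video_sim_spec(fs_percent = 8, seed = 3, noise_sd = 0))
  rev_px <- sim$stack$pixels[rev(seq_len(n_frames(sim$stack))), , ]
  rev_stack <- frame_stack(rev_px, sim$stack$frame_interval)
  roi <- sim$rois[[1]]
  axis <- sim$rois[[3]]$geometry$line
  fwd <- track_tail(sim$stack, roi, axis)
  bwd <- track_tail(rev_stack, roi, axis)
  expected <- rev(fwd$displacement_px) - fwd$displacement_px[n_frames(sim$stack)]
  expect_true(max(abs(bwd$displacement_px - expected)) < 0.2)
})
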