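test_that("constant ROIs normalise to f/f0 of exactly 1", {
  px <- array(20, dim = c(10, 32, 48))
  px[, 5:20, 5:20] <- 100
  stk <- frame_stack(px, 0.025)
  sig <- roi_spec("signal1", "signal", rect = c(4, 4, 16, 16))
  bg <- roi_spec("bg1", "background", rect = c(4, 30, 16, 10))
  tr <- extract_trace(stk, sig, bg)
  expect_equal(tr$f_over_f0, rep(1, 10), tolerance = 1e-12)
  expect_equal(attr(tr, "f0_value"), 80)

  tr2 <- extract_trace(stk, sig)  # no background ROI
  expect_equal(tr2$f_over_f0, rep(1, 10), tolerance = 1e-12)
})

test_that("extraction matches direct arithmetic on generator ROI means", {
  st <- simulate_trace(trace_sim_spec(n_frames = 80, seed = 4, noise_sd = 0))
  fsim <- simulate_fluorescence_stack(st$trace)
  tr <- extract_trace(fsim$stack, fsim$rois[[1]], fsim$rois[[2]])
  f_raw <- fsim$truth$signal_mean - fsim$truth$background_mean
  n_low <- ceiling(length(f_raw) * 0.1)
  f0 <- mean(sort(f_raw)[seq_len(n_low)])
  expect_equal(tr$f_over_f0, f_raw / f0, tolerance = 1e-9)
})

test_that("a dominant background forces an interpretable error", {
  px <- array(10, dim = c(5, 16, 32))
  stk <- frame_stack(px, 0.025)
  sig <- roi_spec("signal1", "signal", rect = c(2, 2, 8, 8))
  bg <- roi_spec("bg1", "background", rect = c(2, 20, 8, 8))
  px2 <- px; px2[, 3:10, 21:28] <- 50
  stk2 <- frame_stack(px2, 0.025)
  expect_error(extract_trace(stk2, sig, bg), "background ROI")
})

test_that("linear detrending removes a pure ramp and preserves the mean", {
  t <- (0:99) * 0.025
  ramp <- make_fluorescence_trace(t, seq(1.0, 1.5, length.out = 100))
  out <- detrend_trace(ramp, "linear")
  expect_equal(out$f_over_f0, rep(1.25, 100), tolerance = 1e-9)
  expect_true(attr(out, "detrended"))

  # idempotence on trend-free data
  st <- simulate_trace(trace_sim_spec(seed = 9, noise_sd = 0))
  once <- detrend_trace(st$trace, "linear")
  twice <- detrend_trace(once, "linear")
  expect_equal(twice$f_over_f0, once$f_over_f0, tolerance = 1e-6)

  expect_error(detrend_trace(make_fluorescence_trace(t[1:5], rep(1, 5)),
                             "polynomial", order = 10), "order")
})

test_that("drifting traces recover the amplitudes of their drift-free twin", {
  spec_clean <- trace_sim_spec(seed = 21, noise_sd = 0.01)
  spec_drift <- trace_sim_spec(seed = 21, noise_sd = 0.01, drift_slope = 0.02)
  clean <- simulate_trace(spec_clean)$trace
  drift <- simulate_trace(spec_drift)$trace

  analyse <- function(tr) {
    tr <- detrend_trace(tr, "linear")
    lv <- estimate_state_levels(tr)
    m <- transient_metrics(detect_transitions(tr, lv), tr)
    mean(m$amplitude_span[!m$incomplete])
  }
  expect_equal(analyse(drift), analyse(clean), tolerance = 0.02)
})

test_that("histogram state levels recover square-wave levels", {
  y <- rep(c(1, 2), 50)
  lv <- estimate_state_levels(make_fluorescence_trace((0:99) * 0.025, y))
  bw <- lv$bin_width
  expect_equal(lv$low, 1, tolerance = bw / 2 + 1e-12)
  expect_equal(lv$high, 2, tolerance = bw / 2 + 1e-12)
  expect_equal(unname(lv$reference_levels), c(1.1, 1.5, 1.9),
               tolerance = bw)

  for (s in 1:3) {
    yn <- y + withr::with_seed(s, rnorm(100, 0, 0.01))
    lvn <- estimate_state_levels(make_fluorescence_trace((0:99) * 0.025, yn))
    expect_equal(lvn$low, 1, tolerance = 0.03)
    expect_equal(lvn$high, 2, tolerance = 0.03)
  }

  expect_error(estimate_state_levels(
    make_fluorescence_trace((0:9) * 0.025, rep(1, 10))), "bi-level")
})

# piecewise-linear trapezoid sampled on the frame grid; closed-form
# crossing of level L on a linear edge from (t0,y0) to (t1,y1)
trapezoid_trace <- function() {
  dt <- 0.025
  t <- seq(0, 5 - dt, by = dt)
  y <- numeric(length(t))
  for (k in 0:4) {
    o <- k  # base from o to o+0.3, rise to o+0.5, plateau to o+0.7, fall to o+0.95
    seg <- function(from, to, v0, v1) {
      i <- t >= from & t < to
      y[i] <<- v0 + (v1 - v0) * (t[i] - from) / (to - from)
    }
    seg(o, o + 0.3, 1, 1)
    seg(o + 0.3, o + 0.5, 1, 2)
    seg(o + 0.5, o + 0.7, 2, 2)
    seg(o + 0.7, o + 0.95, 2, 1)
    seg(o + 0.95, o + 1, 1, 1)
  }
  make_fluorescence_trace(t, y)
}

test_that("trapezoid crossings equal closed-form line intersections", {
  tr <- trapezoid_trace()
  lv <- state_levels(1, 2)
  trans <- detect_transitions(tr, lv)
  complete <- trans[!trans$incomplete, ]
  expect_gte(nrow(complete), 4L)
  for (i in seq_len(nrow(complete))) {
    o <- complete$transient[i] - 1
    # rise: y = 1 + (t - (o+0.3))/0.2; fall: y = 2 - (t - (o+0.7))/0.25
    expect_equal(complete$t_r10[i], o + 0.3 + 0.1 * 0.2, tolerance = 1e-9)
    expect_equal(complete$t_r50[i], o + 0.3 + 0.5 * 0.2, tolerance = 1e-9)
    expect_equal(complete$t_r90[i], o + 0.3 + 0.9 * 0.2, tolerance = 1e-9)
    expect_equal(complete$t_f90[i], o + 0.7 + 0.1 * 0.25, tolerance = 1e-9)
    expect_equal(complete$t_f50[i], o + 0.7 + 0.5 * 0.25, tolerance = 1e-9)
    expect_equal(complete$t_f10[i], o + 0.7 + 0.9 * 0.25, tolerance = 1e-9)
  }
})

test_that("exponential decays cross reference levels at tau*log ratios", {
  dt <- 0.025
  t <- seq(0, 2 - dt, by = dt)
  tau_e <- 0.15; tp <- 0.2
  y <- ifelse(t < tp, 1 + pmax(t - (tp - 0.05), 0) / 0.05,
              1 + exp(-(t - tp) / tau_e))
  tr <- make_fluorescence_trace(t, y)
  trans <- detect_transitions(tr, state_levels(1, 2), refine = FALSE)
  m <- transient_metrics(trans, tr)
  expect_equal(m$tau_fall_10[1], tau_e * log(10), tolerance = dt)
  expect_equal(m$tau_fall_50[1], tau_e * log(2), tolerance = dt)
})

test_that("a linear rise yields exact tau-to-peak at each reference level", {
  dt <- 0.001
  t <- seq(0, 0.5, by = dt)
  y <- ifelse(t < 0.1, 1, ifelse(t < 0.3, 1 + (t - 0.1) / 0.2, 2))
  tr <- make_fluorescence_trace(t, y)
  trans <- detect_transitions(tr, state_levels(1, 2), refine = FALSE)
  m <- transient_metrics(trans, tr)
  # onset is the local minimum before the rise; the base is flat so the
  # anchor time is within the base segment and tau counts from the rise foot
  expect_equal(m$t_r10[1] - 0.1, 0.02, tolerance = 1e-6)
  expect_equal(m$t_r50[1] - 0.1, 0.10, tolerance = 1e-6)
  expect_equal(m$t_r90[1] - 0.1, 0.18, tolerance = 1e-6)
})

test_that("a trace truncated mid-plateau flags its final rise incomplete", {
  dt <- 0.025
  t <- seq(0, 2.2, by = dt)
  y <- numeric(length(t)) + 1
  y[t >= 0.3 & t < 0.5] <- 1 + (t[t >= 0.3 & t < 0.5] - 0.3) / 0.2
  y[t >= 0.5 & t < 0.7] <- 2
  y[t >= 0.7 & t < 0.95] <- 2 - (t[t >= 0.7 & t < 0.95] - 0.7) / 0.25
  y[t >= 1.5] <- pmin(1 + (t[t >= 1.5] - 1.5) / 0.2, 2)  # ends on the plateau
  tr <- make_fluorescence_trace(t, y)
  trans <- detect_transitions(tr, state_levels(1, 2))
  expect_equal(nrow(trans), 2L)
  expect_false(trans$incomplete[1])
  expect_true(trans$incomplete[2])
  expect_true(all(is.na(trans$t_f10[2])))

  m <- transient_metrics(trans, tr)
  s <- summarize_transients(suppressWarnings(discard_outliers(m)))
  expect_equal(s$n_incomplete, 1L)
  expect_equal(s$n_retained, 1L)
  # F_max excludes the incomplete transient
  expect_equal(s$F_max, m$amplitude_span[1])
})

test_that("the 3-MAD rule flags gross outliers and spares clean cohorts", {
  base <- tibble::tibble(
    transient = 1:5,
    amplitude_span = c(1.0, 1.02, 0.98, 1.01, 3.5),
    fall_90_10 = rep(0.3, 5),
    incomplete = FALSE)
  attr(base, "ref_percents") <- c(10, 50, 90)
  out <- discard_outliers(base)
  expect_equal(out$outliers$transient, 5L)
  expect_equal(nrow(out$retained), 4L)

  same <- base
  same$amplitude_span <- rep(1, 5)
  out2 <- discard_outliers(same)
  expect_equal(nrow(out2$outliers), 0L)
})

test_that("an injected half-amplitude beat is the one flagged", {
  st <- simulate_trace(trace_sim_spec(amplitude = c(1.5, 1.5, 0.75, 1.5, 1.5),
                                      noise_sd = 0.02, seed = 6))
  lv <- estimate_state_levels(st$trace)
  m <- transient_metrics(detect_transitions(st$trace, lv), st$trace)
  out <- discard_outliers(m)
  expect_equal(out$outliers$transient, 3L)

  # brute-force reimplementation of the rule on the same metrics
  complete <- m[!m$incomplete, ]
  med_amp <- median(complete$amplitude_span, na.rm = TRUE)
  med_fall <- median(complete$fall_90_10, na.rm = TRUE)
  mad_amp <- 1.4826 * median(abs(complete$amplitude_span - med_amp), na.rm = TRUE)
  mad_fall <- 1.4826 * median(abs(complete$fall_90_10 - med_fall), na.rm = TRUE)
  flag_bf <- vapply(seq_len(nrow(complete)), function(i) {
    fall_i <- complete$fall_90_10[i]
    abs(complete$amplitude_span[i] - med_amp) > 3 * mad_amp ||
      (!is.na(fall_i) && abs(fall_i - med_fall) > 3 * mad_fall)
  }, logical(1))
  expect_equal(sort(out$outliers$transient), complete$transient[flag_bf])
})

test_that("transient summaries report F_max, SEM and beat-to-beat rows", {
  m <- tibble::tibble(
    transient = 1:3,
    amplitude_span = c(0.8, 1.0, 1.2),
    fall_90_10 = c(0.3, 0.31, 0.29),
    incomplete = FALSE)
  attr(m, "ref_percents") <- c(10, 50, 90)
  s <- summarize_transients(discard_outliers(m))
  expect_equal(s$F_max, 1.0)
  amp_row <- s$stats[s$stats$metric == "amplitude_span", ]
  expect_equal(amp_row$sem, 0.11547, tolerance = 1e-4)
  expect_equal(nrow(s$beat_to_beat), 3L)

  single <- m[1, ]
  attr(single, "ref_percents") <- c(10, 50, 90)
  s1 <- summarize_transients(suppressWarnings(discard_outliers(single)))
  expect_true(is.na(s1$stats$sem[1]))
  expect_equal(glance(s1)$n_retained, 1L)
})

test_that("F_max estimates sit within the sampling-error bound", {
  recs <- vapply(1:5, function(s) {
    st <- simulate_trace(trace_sim_spec(amplitude = 1.5, noise_sd = 0.02,
                                        seed = s))
    lv <- estimate_state_levels(st$trace)
    m <- transient_metrics(detect_transitions(st$trace, lv), st$trace)
    summarize_transients(discard_outliers(m))$F_max
  }, numeric(1))
  truth <- mean(simulate_trace(trace_sim_spec(amplitude = 1.5, seed = 1)
                               )$truth$beats$amplitude_span)
  expect_true(all(abs(recs - truth) < 3 * 0.02 / sqrt(5) + 0.01))
})

test_that("crossings are ordered and equivariant to shift and scale", {
  st <- simulate_trace(trace_sim_spec(seed = 12, noise_sd = 0.01))
  tr <- st$trace
  lv <- estimate_state_levels(tr)
  m <- transient_metrics(detect_transitions(tr, lv), tr)
  ok <- m[!m$incomplete, ]
  for (i in seq_len(nrow(ok))) {
    expect_true(ok$t_r10[i] <= ok$t_r50[i])
    expect_true(ok$t_r50[i] <= ok$t_r90[i])
    expect_true(ok$t_r90[i] <= ok$peak_time_s[i])
    expect_true(ok$peak_time_s[i] <= ok$t_f90[i])
    expect_true(ok$t_f90[i] <= ok$t_f50[i])
    expect_true(ok$t_f50[i] <= ok$t_f10[i])
  }

  # time shift moves every crossing by exactly dt_shift
  dt_shift <- 0.4
  shifted <- make_fluorescence_trace(tr$time_s + dt_shift, tr$f_over_f0)
  m2 <- transient_metrics(detect_transitions(shifted, lv), shifted)
  cross_cols <- grep("^t_[rf]", names(m), value = TRUE)
  for (cn in cross_cols)
    expect_equal(m2[[cn]], m[[cn]] + dt_shift, tolerance = 1e-9)

  # amplitude scale: spans scale, crossing times unchanged
  c_scale <- 2.5
  scaled <- make_fluorescence_trace(tr$time_s,
                                    lv$low + c_scale * (tr$f_over_f0 - lv$low))
  lvs <- estimate_state_levels(scaled)
  m3 <- transient_metrics(detect_transitions(scaled, lvs), scaled)
  expect_equal(nrow(m3), nrow(m))
  keep <- !m$incomplete & !m3$incomplete
  expect_equal(m3$amplitude_span[keep], c_scale * m$amplitude_span[keep],
               tolerance = 1e-6 + 0.02)
  for (cn in cross_cols)
    expect_equal(m3[[cn]][keep], m[[cn]][keep], tolerance = 0.03)
})

test_that("the full calcium pipeline runs from stack to summary", {
  st <- simulate_trace(trace_sim_spec(seed = 30))
  fsim <- simulate_fluorescence_stack(st$trace)
  res <- analyze_calcium(fsim$stack, fsim$rois, pacing_hz = 1)
  expect_s3_class(res, "calcium_analysis")
  expect_equal(res$summary$n_transients, 5L)
  expect_equal(glance(res)$F_max, res$summary$F_max)
  expect_s3_class(tidy(res), "tbl_df")
  p <- autoplot(res$trace, transients = res$metrics)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_beat_variability(res$metrics), "ggplot")
})
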