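new_fluorescence_trace <- function(time_s, f_over_f0, f0_value, detrended,
                                   provenance = NULL) {
  if (!all(is.finite(f_over_f0))) abort_input("fluorescence values must be finite")
  if (f0_value <= 0) abort_input("f0 must be positive")
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        f_over_f0 = as.numeric(f_over_f0))
  attr(out, "f0_value") <- f0_value
  attr(out, "detrended") <- isTRUE(detrended)
  attr(out, "provenance") <- provenance
  class(out) <- c("fluorescence_trace", class(out))
  out
}

#' Extract an f/f0 fluorescence trace from a stack
#'
#' Per frame, the raw fluorescence is the mean over the signal ROI minus the
#' mean over the background ROI (zero if no background ROI is given). The
#' baseline divisor f0 is the mean of the raw values over the dimmest tenth
#' of frames, so the resting level maps to f/f0 of about 1 regardless of dye
#' loading or gain.
#'
#' @param stack a [frame_stack()].
#' @param signal a rectangular [roi_spec()] with role `"signal"`.
#' @param background optional rectangular [roi_spec()] with role
#'   `"background"`.
#' @return A `fluorescence_trace` tibble (`time_s`, `f_over_f0`) with the
#'   f0 divisor stored in `attr(, "f0_value")`.
#' @export
extract_trace <- function(stack, signal, background = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  validate_roi_bounds(signal, frame_dim(stack))
  if (!is.null(background)) validate_roi_bounds(background, frame_dim(stack))
  nf <- n_frames(stack)
  f_raw <- vapply(seq_len(nf), function(k) {
    s <- mean(roi_pixels(stack, signal, k))
    b <- if (is.null(background)) 0 else mean(roi_pixels(stack, background, k))
    s - b
  }, numeric(1L))
  n_low <- max(1L, ceiling(nf * 0.1))
  f0 <- mean(sort(f_raw)[seq_len(n_low)])
  if (f0 <= 0)
    abort_input(paste0("baseline f0 is not positive after background ",
                       "subtraction; review the background ROI"))
  new_fluorescence_trace(stack_time(stack), f_raw / f0, f0_value = f0,
                         detrended = FALSE,
                         provenance = sprintf("%s / ROI %s", stack$origin_label,
                                              signal$label))
}

#' Remove slow baseline drift from a fluorescence trace
#'
#' Fits a least-squares polynomial trend of the chosen order against time and
#' subtracts it, then adds the pre-detrend global mean back so the absolute
#' f/f0 level is preserved (a resting trace stays near 1).
#'
#' @param trace a `fluorescence_trace`.
#' @param method `"linear"`, `"polynomial"`, or `"none"`.
#' @param order polynomial order when `method = "polynomial"`.
#' @return The detrended `fluorescence_trace` (`attr(, "detrended")` set).
#' @export
detrend_trace <- function(trace, method = c("linear", "polynomial", "none"),
                          order = 2L) {
  method <- match.arg(method)
  if (method == "none") return(trace)
  y <- trace$f_over_f0
  t <- trace$time_s
  if (length(y) < 3L) abort_input("detrending needs at least 3 samples")
  k <- if (method == "linear") 1L else as.integer(order)
  if (k >= length(y)) abort_input("polynomial order must be below the trace length")
  fit <- stats::lm(y ~ stats::poly(t, k, raw = TRUE))
  out <- y - stats::fitted(fit) + mean(y)
  new_fluorescence_trace(t, out, f0_value = attr(trace, "f0_value") %||% 1,
                         detrended = TRUE,
                         provenance = attr(trace, "provenance"))
}

#' Construct state levels directly
#'
#' For waveforms whose true levels are known (calibration signals, analytic
#' test waveforms) the estimation step can be bypassed by supplying the low
#' and high state levels explicitly.
#'
#' @param low,high the two state levels (`high > low`).
#' @param ref_percents reference-level percentages (default 10, 50, 90).
#' @return An object of class `state_levels`.
#' @export
state_levels <- function(low, high, ref_percents = c(10, 50, 90)) {
  if (!is_scalar_number(low) || !is_scalar_number(high) || high <= low)
    abort_input("`high` must exceed `low`")
  a <- high - low
  structure(list(low = low, high = high, amplitude = a,
                 reference_levels = stats::setNames(
                   low + ref_percents / 100 * a, paste0("p", ref_percents)),
                 ref_percents = ref_percents, bin_width = 0),
            class = "state_levels")
}

#' Histogram state levels of a bi-level waveform
#'
#' The two state levels of a transient train (baseline and peak plateau) are
#' estimated by the histogram mode method of bi-level waveform metrology: the
#' data range is split at its midpoint, and each state level is the center of
#' the most populated histogram bin in its half (ties resolve to the lower
#' bin). Reference levels are placed at `S1 + p * (S2 - S1)` for each
#' requested fraction `p`.
#'
#' @param trace a `fluorescence_trace` (or any tibble with `f_over_f0`).
#' @param bins histogram bin count (default 100).
#' @param ref_percents reference-level percentages (default 10, 50, 90).
#' @return An object of class `state_levels`: list with `low`, `high`,
#'   `amplitude`, and named vector `reference_levels`.
#' @export
estimate_state_levels <- function(trace, bins = 100L,
                                  ref_percents = c(10, 50, 90)) {
  y <- if (is.data.frame(trace)) trace$f_over_f0 else as.numeric(trace)
  rng <- range(y)
  if (diff(rng) == 0)
    abort_input("no bi-level structure: the trace is single-valued")
  edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  counts <- graphics::hist(y, breaks = edges, plot = FALSE)$counts
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  mid <- mean(rng)
  lower <- centers < mid
  s1 <- centers[lower][which.max(counts[lower])]
  s2 <- centers[!lower][which.max(counts[!lower])]
  a <- s2 - s1
  refs <- stats::setNames(s1 + ref_percents / 100 * a,
                          paste0("p", ref_percents))
  structure(list(low = s1, high = s2, amplitude = a,
                 reference_levels = refs, ref_percents = ref_percents,
                 bin_width = diff(edges[1:2])),
            class = "state_levels")
}

#' @export
print.state_levels <- function(x, ...) {
  cat(sprintf("<state_levels> low %.4g  high %.4g  amplitude %.4g\n",
              x$low, x$high, x$amplitude))
  cat("  reference levels:",
      paste(sprintf("%s=%.4g", names(x$reference_levels), x$reference_levels),
            collapse = "  "), "\n")
  invisible(x)
}

# baseline anchor read-out: mean over the anchor index and the two frames
# before it. Averaging suppresses the negative bias of reading a noisy local
# minimum sample; the window must not extend past the anchor because the
# upstroke can be only 2-3 frames wide.
anchor_value <- function(y, k) {
  mean(y[max(1L, k - 2L):k])
}

# 3-point moving average with one-sided ends
smoothed3 <- function(y) {
  n <- length(y)
  if (n < 3L) return(y)
  out <- y
  out[2:(n - 1L)] <- (y[1:(n - 2L)] + y[2:(n - 1L)] + y[3:n]) / 3
  out[1L] <- mean(y[1:2]); out[n] <- mean(y[(n - 1L):n])
  out
}

# baseline anchor inside a window: argmin of the lightly smoothed trace, read
# from the smoothed values. Exact on flat bases (unlike a trailing average,
# which can straddle the preceding decay); suppresses minimum-picking noise
# bias on real data.
anchor_at <- function(y, win) {
  sm <- smoothed3(y[win])
  j <- which.min(sm)
  list(idx = win[j], value = sm[j])
}

# interpolated time at which y crosses `level` between samples i and i+1
interp_crossing <- function(t, y, i, level) {
  t[i] + (t[i + 1L] - t[i]) * (level - y[i]) / (y[i + 1L] - y[i])
}

#' Locate transitions and their reference-level crossings
#'
#' Rising edges are located by upward crossings of the 50% level, falling
#' edges by downward crossings; edges are paired rise-to-fall. For every
#' transient each requested reference level is crossed by linear
#' interpolation between the bracketing samples (no model fitting). The peak
#' is the maximum sample between the paired 50% crossings. A final rise with
#' no completed fall -- or a transient whose crossings cannot all be located
#' inside the record -- is flagged `incomplete`.
#'
#' Histogram state levels assume the waveform dwells at both states. A
#' transient train dwells only at baseline -- the peaks are visited briefly --
#' so with `refine = TRUE` (the default) a second pass re-anchors the
#' reference levels at the cohort medians of the per-transient peaks (high
#' state) and pre-rise minima (low state) found in the first pass, and the
#' crossings are recomputed. For waveforms that do dwell at both levels
#' (square or trapezoid pulses) the refined levels coincide with the
#' histogram levels and the result is unchanged.
#'
#' @param trace a `fluorescence_trace`.
#' @param levels a `state_levels` object.
#' @param refine re-anchor reference levels on first-pass transients
#'   (default `TRUE`).
#' @return A tibble with one row per transient: `transient`, rise crossing
#'   times `t_r<p>`, `peak_time_s`, `peak_value`, fall crossing times
#'   `t_f<p>`, and `incomplete`. The levels actually used are stored in
#'   `attr(, "levels")`.
#' @export
detect_transitions <- function(trace, levels, refine = TRUE) {
  stopifnot(inherits(levels, "state_levels"))
  out <- detect_transitions_once(trace, levels)
  if (!refine || nrow(out) == 0L) return(out)
  refined <- refine_state_levels(trace, out, levels)
  if (is.null(refined)) return(out)
  detect_transitions_once(trace, refined)
}

# cohort-median re-anchoring of the state levels on detected transients
refine_state_levels <- function(trace, transients, levels) {
  t <- trace$time_s
  y <- trace$f_over_f0
  peaks <- transients$peak_value
  pre_min <- vapply(seq_len(nrow(transients)), function(j) {
    lo <- if (j > 1L) transients$peak_time_s[j - 1L] else t[1L]
    win <- which(t >= lo & t <= transients$peak_time_s[j])
    if (length(win) == 0L) return(NA_real_)
    anchor_at(y, win)$value
  }, numeric(1L))
  s1 <- stats::median(pre_min, na.rm = TRUE)
  s2 <- stats::median(peaks, na.rm = TRUE)
  if (!is.finite(s1) || !is.finite(s2) || s2 <= s1) return(NULL)
  pct <- levels$ref_percents
  structure(list(low = s1, high = s2, amplitude = s2 - s1,
                 reference_levels = stats::setNames(
                   s1 + pct / 100 * (s2 - s1), paste0("p", pct)),
                 ref_percents = pct, bin_width = levels$bin_width),
            class = "state_levels")
}

# Single detection pass. Edges are found with hysteresis: a rising edge
# requires the signal to travel from below the lowest reference level (the
# arm level) to above a 35%-of-span trigger, and a falling edge must return
# below the arm level -- so sample noise around a reference level cannot
# fabricate transients, while aberrant low-amplitude beats (the outlier
# candidates) are still detected. Each limb is then projected onto its
# isotonic (monotone) regression before the reference levels are crossed by
# linear interpolation; for noiseless monotone limbs the projection is the
# identity, so analytic waveforms are measured exactly. Reference levels a
# transient's peak never reaches yield NA crossing times; `incomplete` is
# reserved for transients cut off by the end of the record.
detect_transitions_once <- function(trace, levels) {
  t <- trace$time_s
  y <- trace$f_over_f0
  n <- length(y)
  pct <- sort(levels$ref_percents)
  ref <- levels$low + pct / 100 * levels$amplitude
  lo_g <- ref[1L]
  hi_g <- levels$low + max(0.35, pct[1L] / 100 + 0.2) * levels$amplitude

  edges <- hysteresis_edges(y, lo_g, hi_g)
  rises <- edges$rises
  if (length(rises) == 0L) return(empty_transitions(levels$ref_percents))
  falls <- edges$falls

  rows <- purrr::map_dfr(seq_along(rises), function(j) {
    arm <- rises[[j]]  # c(i_low, i_high): armed-low sample, first-above-trigger
    nxt_fall <- Filter(function(f) f[1L] >= arm[2L], falls)
    fall <- if (length(nxt_fall)) nxt_fall[[1L]] else NULL
    incomplete <- is.null(fall)

    pk_hi <- if (!incomplete) fall[1L] else
      if (j < length(rises)) rises[[j + 1L]][1L] else n
    pk_span <- arm[2L]:pk_hi
    pk_idx <- pk_span[which.max(y[pk_span])]

    # rising limb: from the pre-rise armed sample up to the peak
    rise_seg <- arm[1L]:pk_idx
    t_rise <- limb_crossings(t[rise_seg], iso_fit(y[rise_seg], increasing = TRUE),
                             ref)

    # falling limb: from the peak to the re-arming of the low state
    t_fall <- if (incomplete) rep(NA_real_, length(ref)) else {
      fall_seg <- pk_idx:fall[2L]
      # reverse time so the fall becomes a rise; negate back afterwards
      -limb_crossings(rev(-t[fall_seg]),
                      iso_fit(rev(y[fall_seg]), increasing = TRUE), ref)
    }

    out <- tibble::tibble(transient = j)
    for (i in seq_along(pct)) out[[paste0("t_r", pct[i])]] <- t_rise[i]
    out$peak_time_s <- t[pk_idx]
    out$peak_value <- y[pk_idx]
    for (i in rev(seq_along(pct))) out[[paste0("t_f", pct[i])]] <- t_fall[i]
    out$incomplete <- incomplete
    out
  })
  rows$transient <- seq_len(nrow(rows))
  attr(rows, "ref_percents") <- pct
  attr(rows, "levels") <- levels
  rows
}

# hysteresis edge finder: returns rising edges as (last sample below lo_g,
# first sample above hi_g) and falling edges as (last sample above hi_g,
# first sample below lo_g)
hysteresis_edges <- function(y, lo_g, hi_g) {
  rises <- list(); falls <- list()
  state <- if (y[1L] <= lo_g) "low" else if (y[1L] >= hi_g) "high" else "mid"
  last_low <- if (state == "low") 1L else NA_integer_
  last_high <- if (state == "high") 1L else NA_integer_
  for (i in 2:length(y)) {
    if (y[i] <= lo_g) {
      if (state == "high" && !is.na(last_high))
        falls[[length(falls) + 1L]] <- c(last_high, i)
      last_low <- i
      state <- "low"
    } else if (y[i] >= hi_g) {
      if (state == "low" && !is.na(last_low))
        rises[[length(rises) + 1L]] <- c(last_low, i)
      last_high <- i
      state <- "high"
    }
  }
  list(rises = rises, falls = falls)
}

# isotonic projection of one limb; identity for already-monotone data
iso_fit <- function(y, increasing = TRUE) {
  if (length(y) < 2L) return(y)
  if (increasing) stats::isoreg(y)$yf else -stats::isoreg(-y)$yf
}

# interpolated crossing times of each level on a nondecreasing limb
limb_crossings <- function(t, yf, ref) {
  vapply(ref, function(L) {
    i <- which(yf[-length(yf)] < L & yf[-1L] >= L)[1L]
    if (is.na(i)) return(NA_real_)
    t[i] + (t[i + 1L] - t[i]) * (L - yf[i]) / (yf[i + 1L] - yf[i])
  }, numeric(1L))
}

empty_transitions <- function(pct) {
  pct <- sort(pct)
  out <- tibble::tibble(transient = integer(0))
  for (p in pct) out[[paste0("t_r", p)]] <- numeric(0)
  out$peak_time_s <- numeric(0)
  out$peak_value <- numeric(0)
  for (p in rev(pct)) out[[paste0("t_f", p)]] <- numeric(0)
  out$incomplete <- logical(0)
  attr(out, "ref_percents") <- pct
  out
}

#' Per-transient tau statistics and amplitudes
#'
#' Anchors each transient at its beat onset -- the local minimum of the trace
#' preceding the rise, or the latest supplied pacing time before it -- and
#' derives the tau read-outs: `tau_to_peak_<p>` (onset to rising crossing),
#' `tau_fall_<p>` (peak to falling crossing), `rise_10_90`, `fall_90_10`,
#' and `amplitude_span` (peak value minus onset value).
#'
#' @param transients output of [detect_transitions()].
#' @param trace the `fluorescence_trace` the transients came from.
#' @param onsets optional vector of pacing onset times (seconds); when given
#'   they override the local-minimum anchor.
#' @return The transient tibble augmented with onset and tau columns.
#' @export
transient_metrics <- function(transients, trace, onsets = NULL) {
  pct <- attr(transients, "ref_percents") %||% c(10, 50, 90)
  t <- trace$time_s
  y <- trace$f_over_f0
  if (nrow(transients) == 0L) return(transients)
  lo_p <- pct[1L]; hi_p <- pct[length(pct)]

  out <- purrr::map_dfr(seq_len(nrow(transients)), function(j) {
    row <- transients[j, ]
    first_rise <- row[[paste0("t_r", lo_p)]]
    if (is.na(first_rise)) first_rise <- row$peak_time_s
    if (!is.null(onsets)) {
      before <- onsets[onsets <= first_rise]
      if (length(before) == 0L) {
        row$incomplete <- TRUE
        onset_t <- NA_real_
      } else onset_t <- max(before)
      onset_v <- if (is.na(onset_t)) NA_real_ else
        anchor_value(y, which.min(abs(t - onset_t)))
    } else {
      win_start <- if (j > 1L) {
        prev <- transients[[paste0("t_f", lo_p)]][j - 1L]
        if (is.na(prev)) transients$peak_time_s[j - 1L] else prev
      } else t[1L]
      win <- which(t >= win_start & t <= first_rise)
      if (length(win) == 0L) {
        row$incomplete <- TRUE
        onset_t <- NA_real_; onset_v <- NA_real_
      } else {
        a <- anchor_at(y, win)
        onset_t <- t[a$idx]; onset_v <- a$value
      }
    }
    row$onset_time_s <- onset_t
    row$onset_value <- onset_v
    for (p in pct)
      row[[paste0("tau_to_peak_", p)]] <- row[[paste0("t_r", p)]] - onset_t
    for (p in pct)
      row[[paste0("tau_fall_", p)]] <- row[[paste0("t_f", p)]] - row$peak_time_s
    row[[sprintf("rise_%d_%d", lo_p, hi_p)]] <-
      row[[paste0("t_r", hi_p)]] - row[[paste0("t_r", lo_p)]]
    row[[sprintf("fall_%d_%d", hi_p, lo_p)]] <-
      row[[paste0("t_f", lo_p)]] - row[[paste0("t_f", hi_p)]]
    row$amplitude_span <- row$peak_value - onset_v
    row
  })
  attr(out, "ref_percents") <- pct
  out
}

#' Flag statistically outlying transients
#'
#' A complete transient is flagged as an outlier when its amplitude span or
#' its fall duration (90% to 10% crossing) deviates from the cohort median
#' by more than 3 scaled median absolute deviations (MAD x 1.4826). With
#' fewer than 3 complete transients no flagging is attempted. Incomplete
#' transients are always excluded from statistics but are never counted as
#' outliers.
#'
#' @param metrics output of [transient_metrics()].
#' @param n_mad flag threshold in scaled MADs (default 3).
#' @return A list with tibbles `retained`, `outliers`, `incomplete`.
#' @export
discard_outliers <- function(metrics, n_mad = 3) {
  pct <- attr(metrics, "ref_percents") %||% c(10, 50, 90)
  fall_col <- sprintf("fall_%d_%d", pct[length(pct)], pct[1L])
  complete <- metrics[!metrics$incomplete, ]
  incomplete <- metrics[metrics$incomplete, ]
  if (nrow(complete) < 3L) {
    if (nrow(complete) > 0L)
      warning("fewer than 3 complete transients: outlier screening skipped",
              call. = FALSE)
    complete$outlier <- rep(FALSE, nrow(complete))
    return(list(retained = complete, outliers = complete[0, ],
                incomplete = incomplete))
  }
  robust_flag <- function(x) {
    med <- stats::median(x, na.rm = TRUE)
    s <- stats::mad(x, na.rm = TRUE)  # scaled by 1.4826
    out <- abs(x - med) > n_mad * s
    out[is.na(out)] <- FALSE  # a crossing the peak never reached cannot vote
    out
  }
  flag <- robust_flag(complete$amplitude_span) | robust_flag(complete[[fall_col]])
  complete$outlier <- flag
  list(retained = complete[!flag, ], outliers = complete[flag, ],
       incomplete = incomplete)
}

#' Summarise a transient train
#'
#' F_max is the mean amplitude span (peak to local baseline) over the
#' retained transients -- the standard transient-amplitude read-out. Every
#' tau metric is reported as mean and SEM over retained transients, and the
#' per-transient (beat-to-beat) table is preserved so variability can be
#' inspected or plotted.
#'
#' @param screened output of [discard_outliers()].
#' @return An object of class `transient_summary`.
#' @export
summarize_transients <- function(screened) {
  retained <- screened$retained
  n_out <- nrow(screened$outliers)
  n_inc <- nrow(screened$incomplete)
  metric_cols <- grep("^(tau_|rise_|fall_|amplitude_)", names(retained),
                      value = TRUE)
  if (nrow(retained) == 0L) {
    warning("no retained transients: summary holds counts only", call. = FALSE)
    stats_tbl <- tibble::tibble(metric = metric_cols, mean = NA_real_,
                                sem = NA_real_, n = 0L)
    f_max <- NA_real_
  } else {
    stats_tbl <- purrr::map_dfr(metric_cols, function(cn) {
      x <- retained[[cn]]
      x <- x[is.finite(x)]
      tibble::tibble(metric = cn, mean = mean(x), sem = sem(x),
                     n = length(x))
    })
    f_max <- mean(retained$amplitude_span)
  }
  structure(list(
    F_max = f_max,
    n_transients = nrow(retained) + n_out + n_inc,
    n_retained = nrow(retained), n_outliers = n_out, n_incomplete = n_inc,
    stats = stats_tbl, beat_to_beat = retained
  ), class = "transient_summary")
}

#' @export
print.transient_summary <- function(x, ...) {
  cat(sprintf(
    "<transient_summary> %d transient(s): %d retained, %d outlier(s), %d incomplete\n",
    x$n_transients, x$n_retained, x$n_outliers, x$n_incomplete))
  cat(sprintf("  F_max (mean peak-to-baseline span): %.4g\n", x$F_max))
  fmt <- x$stats
  for (i in seq_len(nrow(fmt)))
    cat(sprintf("  %-16s %8.4g +/- %.3g (n=%d)\n", fmt$metric[i],
                fmt$mean[i], fmt$sem[i], fmt$n[i]))
  invisible(x)
}

#' Full calcium-transient analysis of one recording
#'
#' Chains extraction, detrending, state-level estimation, transition
#' detection, tau metrology, outlier screening and summary.
#'
#' @param stack a [frame_stack()].
#' @param rois list of [roi_spec()] containing one `signal` (and optionally
#'   one `background`) rectangle.
#' @param detrend `"linear"`, `"polynomial"` or `"none"`.
#' @param ref_percents reference-level percentages.
#' @param pacing_hz optional pacing frequency; onsets at `k / pacing_hz`
#'   override the local-minimum beat anchor.
#' @return A list of class `calcium_analysis` with elements `trace`,
#'   `levels`, `metrics` (per-transient tibble) and `summary`.
#' @export
analyze_calcium <- function(stack, rois, detrend = "linear",
                            ref_percents = c(10, 50, 90), pacing_hz = NULL) {
  roles <- vapply(rois, function(r) r$role, character(1L))
  sig <- rois[roles == "signal"]
  bg <- rois[roles == "background"]
  if (length(sig) != 1L) abort_input("exactly one signal ROI is required")
  trace <- extract_trace(stack, sig[[1L]],
                         if (length(bg) >= 1L) bg[[1L]] else NULL)
  trace <- detrend_trace(trace, detrend)
  levels <- estimate_state_levels(trace, ref_percents = ref_percents)
  trans <- detect_transitions(trace, levels)
  onsets <- if (!is.null(pacing_hz))
    seq(0, max(trace$time_s), by = 1 / pacing_hz) else NULL
  metrics <- transient_metrics(trans, trace, onsets = onsets)
  screened <- discard_outliers(metrics)
  structure(list(trace = trace, levels = levels, metrics = metrics,
                 summary = summarize_transients(screened)),
            class = "calcium_analysis")
}

#' @export
print.calcium_analysis <- function(x, ...) {
  print(x$levels)
  print(x$summary)
  invisible(x)
}
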