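#' Track a cell tail through a video
#'
#' Frame-0 template matching: the tail ROI pixels of the first frame are the
#' template; every frame is searched over a square window of integer shifts
#' (`search_radius` px each way) by normalized cross-correlation (NCC), the
#' integer peak is refined by a 3-point parabolic fit per axis, and the 2-D
#' shift is projected onto the cell-axis unit vector pointing from the tail
#' toward the cell center. Positive displacement therefore means the tail is
#' moving toward the center, i.e. the cell is shortening.
#'
#' NCC is invariant to affine intensity changes, so illumination drift or
#' stack renormalisation cannot bias the displacement.
#'
#' @param stack a [frame_stack()].
#' @param tail_roi a [roi_spec()] with role `"tail"`. Must sit at least
#'   `search_radius` px inside the frame.
#' @param axis 2x2 matrix of axis endpoints (`(row, col)` per row), or an
#'   axis [roi_spec()].
#' @param search_radius integer search half-width in px (default 12).
#' @param min_corr NCC quality floor; if more than 20% of frames peak below
#'   it, tracking is declared failed.
#'
#' @return A tibble of class `displacement_trace` with columns `time_s`,
#'   `displacement_px`, `correlation_peak`.
#' @export
track_tail <- function(stack, tail_roi, axis, search_radius = 12L,
                       min_corr = 0.5) {
  stopifnot(inherits(stack, "frame_stack"))
  if (inherits(axis, "roi_spec")) {
    if (axis$geometry$type != "line") abort_input("`axis` ROI must be a line")
    axis <- axis$geometry$line
  }
  axis <- matrix(as.numeric(axis), nrow = 2L)
  validate_roi_bounds(tail_roi, frame_dim(stack))
  r <- round(tail_roi$geometry$rect)
  hw <- frame_dim(stack)
  R <- as.integer(search_radius)
  if (r[1L] - R < 0 || r[2L] - R < 0 ||
      r[1L] + r[3L] + R > hw[1L] || r[2L] + r[4L] + R > hw[2L])
    abort_input(sprintf(
      "tail ROI '%s' must sit at least %d px (the search radius) inside the frame",
      tail_roi$label, R))

  template <- stack$pixels[1L, (r[1L] + 1L):(r[1L] + r[3L]),
                           (r[2L] + 1L):(r[2L] + r[4L])]
  if (stats::var(as.vector(template)) == 0)
    abort_input(sprintf("tail ROI '%s': flat (zero-variance) template", tail_roi$label))

  # axis unit vector pointing from this tail toward the cell center
  ctr <- roi_center(tail_roi)
  d1 <- sum((ctr - axis[1L, ])^2)
  d2 <- sum((ctr - axis[2L, ])^2)
  near <- if (d1 <= d2) axis[1L, ] else axis[2L, ]
  far <- if (d1 <= d2) axis[2L, ] else axis[1L, ]
  u <- (far - near) / sqrt(sum((far - near)^2))

  nf <- n_frames(stack)
  disp <- numeric(nf)
  peak <- numeric(nf)
  rows <- (r[1L] - R + 1L):(r[1L] + r[3L] + R)
  cols <- (r[2L] - R + 1L):(r[2L] + r[4L] + R)
  for (k in seq_len(nf)) {
    region <- stack$pixels[k, rows, cols]
    ncc <- ncc_map(region, template)
    ij <- arrayInd(which.max(ncc), dim(ncc))
    peak[k] <- ncc[ij]
    shift <- c(ij[1L] - (R + 1L), ij[2L] - (R + 1L)) +
      c(parabolic_offset(ncc, ij, 1L), parabolic_offset(ncc, ij, 2L))
    disp[k] <- sum(shift * u)
  }
  disp <- disp - disp[1L]  # displacement relative to frame 0

  bad <- mean(peak < min_corr)
  if (bad > 0.2)
    abort_input(sprintf(
      "tracking failed for ROI '%s': correlation peak below %.2f in %.0f%% of frames",
      tail_roi$label, min_corr, 100 * bad))

  out <- tibble::tibble(time_s = stack_time(stack), displacement_px = disp,
                        correlation_peak = peak)
  attr(out, "frame_interval") <- stack$frame_interval
  attr(out, "label") <- tail_roi$label
  class(out) <- c("displacement_trace", class(out))
  out
}

# NCC of `template` (h x w) against every h x w window of `region`
# ((h+2R) x (w+2R)); returns a (2R+1) x (2R+1) correlation map.
# Cross-products via 2-D FFT, window sums via integral images.
ncc_map <- function(region, template) {
  h <- nrow(template); w <- ncol(template)
  P1 <- nrow(region); P2 <- ncol(region)
  nu <- P1 - h + 1L; nv <- P2 - w + 1L
  n <- h * w

  tpad <- matrix(0, P1, P2)
  tpad[1:h, 1:w] <- template
  cross <- Re(stats::fft(stats::fft(region) * Conj(stats::fft(tpad)),
                         inverse = TRUE)) / (P1 * P2)
  cross <- cross[1:nu, 1:nv]

  s1 <- window_sums(region, h, w)
  s2 <- window_sums(region^2, h, w)
  tsum <- sum(template)
  tss <- sum(template^2) - tsum^2 / n

  num <- cross - s1 * (tsum / n)
  den2 <- (s2 - s1^2 / n) * tss
  ncc <- num / sqrt(pmax(den2, .Machine$double.eps))
  ncc[den2 <= n * 1e-12 * tss] <- 0  # flat windows carry no signal
  pmin(pmax(ncc, -1), 1)
}

# sums over all h x w windows of m, via a padded integral image
window_sums <- function(m, h, w) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))  # ii[i,j] = sum m[1..i,1..j]
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[2:(nr + 1L), 2:(nc + 1L)] <- cs
  nu <- nr - h + 1L; nv <- nc - w + 1L
  ii[(1L + h):(nu + h), (1L + w):(nv + w)] -
    ii[1:nu, (1L + w):(nv + w)] -
    ii[(1L + h):(nu + h), 1:nv] +
    ii[1:nu, 1:nv]
}

# sub-pixel offset along one axis from a 3-point parabola through the peak
parabolic_offset <- function(m, ij, axis) {
  idx <- ij[axis]
  if (idx <= 1L || idx >= dim(m)[axis]) return(0)
  pick <- function(o) if (axis == 1L) m[idx + o, ij[2L]] else m[ij[1L], idx + o]
  ym <- pick(-1L); y0 <- pick(0L); yp <- pick(1L)
  denom <- ym - 2 * y0 + yp
  if (denom >= 0) return(0)  # not a concave peak
  delta <- 0.5 * (ym - yp) / denom
  max(min(delta, 0.5), -0.5)
}

#' Segment a displacement trace into beats
#'
#' With a known pacing frequency, beats are consecutive windows of
#' `1/pacing_hz` seconds starting at `t = 0` (only complete windows are
#' kept). Without pacing, beats are detected as peaks of `|displacement|`
#' above 50% of the global maximum, thinned so that no two peaks are closer
#' than 0.4 times the median inter-peak interval; windows then run between
#' midpoints of consecutive peaks.
#'
#' @param trace a `displacement_trace` (or any tibble with `time_s` and
#'   `displacement_px`).
#' @param pacing_hz pacing frequency in Hz, or `NULL` for peak detection.
#'
#' @return A tibble with columns `beat`, `t_start`, `t_end` (half-open
#'   windows `[t_start, t_end)`).
#' @export
beat_segment <- function(trace, pacing_hz = NULL) {
  t <- trace$time_s
  y <- trace$displacement_px
  dt <- t[2L] - t[1L]
  if (!is.null(pacing_hz)) {
    stopifnot(pacing_hz > 0)
    period <- 1 / pacing_hz
    # count windows whose span is covered by the sampled record
    n_beats <- floor((t[length(t)] + dt) / period + 1e-9)
    if (n_beats < 1L) abort_input("record shorter than one pacing period")
    return(tibble::tibble(beat = seq_len(n_beats),
                          t_start = (seq_len(n_beats) - 1) * period,
                          t_end = seq_len(n_beats) * period))
  }
  a <- abs(y)
  noise_floor <- 3 * stats::mad(y)
  if (max(a) <= noise_floor || max(a) == 0)
    abort_input("no contraction detected (no peak above the noise floor)")
  thr <- 0.5 * max(a)
  cand <- which(diff(sign(diff(a))) < 0) + 1L
  cand <- cand[a[cand] >= thr]
  if (length(cand) == 0L) abort_input("no contraction detected (no peak above the noise floor)")
  if (length(cand) > 1L) {
    med <- stats::median(diff(t[cand]))
    min_sep <- 0.4 * med
    keep <- order(a[cand], decreasing = TRUE)
    taken <- integer(0)
    for (i in keep) {
      if (all(abs(t[cand[i]] - t[cand[taken]]) >= min_sep)) taken <- c(taken, i)
    }
    cand <- sort(cand[taken])
  }
  edges <- c(t[1L], (t[cand[-length(cand)]] + t[cand[-1L]]) / 2,
             t[length(t)] + dt)
  tibble::tibble(beat = seq_along(cand),
                 t_start = edges[-length(edges)],
                 t_end = edges[-1L])
}

#' Per-beat maximum displacement
#'
#' For each beat window the maximum of `|displacement|` is taken; the
#' summary MD is the arithmetic mean over beats. Using the absolute value
#' makes the result independent of the sign convention of the tail.
#'
#' @param trace a `displacement_trace`.
#' @param beats beat windows from [beat_segment()].
#'
#' @return A list with `md_mean_px` and a per-beat tibble `per_beat`
#'   (`beat`, `md_px`).
#' @export
max_displacement <- function(trace, beats) {
  if (nrow(beats) < 1L) abort_input("at least one beat window is required")
  md <- purrr::map_dbl(seq_len(nrow(beats)), function(i) {
    in_win <- trace$time_s >= beats$t_start[i] & trace$time_s < beats$t_end[i]
    if (!any(in_win)) {
      warning(sprintf("beat %d: empty window, skipped", beats$beat[i]), call. = FALSE)
      return(NA_real_)
    }
    max(abs(trace$displacement_px[in_win]))
  })
  keep <- !is.na(md)
  list(md_mean_px = mean(md[keep]),
       per_beat = tibble::tibble(beat = beats$beat[keep], md_px = md[keep]))
}

#' Fraction shortening
#'
#' `FS = 100 * (MD1 + MD2) / (L0 / 2)` percent, where MD1 and MD2 are the
#' mean maximum displacements of the two tails and L0 the uncontracted cell
#' length, all in pixels. Healthy basal murine myocytes shorten by a few
#' percent; beta-adrenergic stimulation roughly doubles that.
#'
#' @param md1_px,md2_px mean maximum tail displacements, px (>= 0).
#' @param l0_px uncontracted cell length, px (> 0).
#' @return Fraction shortening in percent.
#' @export
#' @examples
#' fraction_shortening(2, 3, 100)   # 10%
fraction_shortening <- function(md1_px, md2_px, l0_px) {
  if (!is_scalar_number(l0_px) || l0_px <= 0)
    abort_input("`l0_px` must be a single positive number")
  if (md1_px < 0 || md2_px < 0) abort_input("displacements must be >= 0")
  100 * (md1_px + md2_px) / (l0_px / 2)
}

#' Peak-based kinematic parameters of a contracting cell
#'
#' Velocity is the central-difference derivative of the displacement trace,
#' acceleration the central difference of the signed velocity. Per tail and
#' per beat the maxima of speed, |acceleration| and squared speed are taken;
#' beat means give the tail's contractility (px/s), force (px/s^2) and
#' contraction energy (px^2/s^2). The total contraction force is the sum
#' over the two tails; contractility and energy are reported as the average
#' of the two tails. These peak-based estimators are this package's
#' operational definitions of the classical kinematic read-outs.
#'
#' @param trace1,trace2 `displacement_trace`s of the two tails (shared
#'   timebase).
#' @param beats beat windows from [beat_segment()].
#' @param smooth apply a Savitzky-Golay filter (window 5, order 2) to the
#'   displacement before differentiating. Off by default.
#'
#' @return A list with `force_total_px_s2`, `contractility_px_s`,
#'   `energy_px2_s2` and a per-tail, per-beat tibble `per_beat`.
#' @export
kinematic_params <- function(trace1, trace2, beats, smooth = FALSE) {
  if (length(trace1$time_s) != length(trace2$time_s) ||
      max(abs(trace1$time_s - trace2$time_s)) > 1e-9)
    abort_input("the two tail traces must share a timebase")
  per_tail <- purrr::map(list(trace1, trace2), function(tr)
    tail_beat_peaks(tr, beats, smooth))
  pb <- dplyr::bind_rows(per_tail[[1L]]$per_beat %>% dplyr::mutate(tail = 1L),
                         per_tail[[2L]]$per_beat %>% dplyr::mutate(tail = 2L))
  list(
    force_total_px_s2 = per_tail[[1L]]$force + per_tail[[2L]]$force,
    contractility_px_s = (per_tail[[1L]]$contractility + per_tail[[2L]]$contractility) / 2,
    energy_px2_s2 = (per_tail[[1L]]$energy + per_tail[[2L]]$energy) / 2,
    per_beat = pb
  )
}

tail_beat_peaks <- function(trace, beats, smooth = FALSE) {
  t <- trace$time_s
  d <- trace$displacement_px
  dt <- t[2L] - t[1L]
  if (isTRUE(smooth) && length(d) >= 5L)
    d <- signal::sgolayfilt(d, p = 2, n = 5)
  v <- finite_diff(d, dt)
  a <- finite_diff(v, dt)
  rows <- purrr::map_dfr(seq_len(nrow(beats)), function(i) {
    in_win <- t >= beats$t_start[i] & t < beats$t_end[i]
    if (sum(in_win) < 3L) {
      warning(sprintf("beat %d: fewer than 3 samples, skipped", beats$beat[i]),
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(beat = beats$beat[i],
                   peak_speed_px_s = max(abs(v[in_win])),
                   peak_accel_px_s2 = max(abs(a[in_win])),
                   peak_speed_sq = max(v[in_win]^2))
  })
  if (nrow(rows) == 0L) abort_input("no beat with enough samples")
  list(force = mean(rows$peak_accel_px_s2),
       contractility = mean(rows$peak_speed_px_s),
       energy = mean(rows$peak_speed_sq),
       per_beat = rows)
}

#' Full shortening analysis of one cell
#'
#' Convenience wrapper: tracks both tails, segments beats, and assembles the
#' kinematic metrics. The ROI list must contain exactly two `tail` ROIs and
#' one `axis` line; `L0` defaults to the axis length.
#'
#' @param stack a [frame_stack()].
#' @param rois list of [roi_spec()] (two tails + one axis at minimum).
#' @param pacing_hz pacing frequency, or `NULL` for peak-based beat
#'   detection.
#' @param l0_px override the uncontracted length; default: axis length.
#' @param smooth passed to [kinematic_params()].
#' @param search_radius passed to [track_tail()].
#'
#' @return An object of class `kinematics_metrics`: a list with fields
#'   `MD1_px`, `MD2_px`, `L0_px`, `FS_percent`, `force_total_px_s2`,
#'   `contractility_px_s`, `energy_px2_s2`, per-beat tibble `per_beat`, and
#'   the two displacement traces in `traces`.
#' @export
analyze_shortening <- function(stack, rois, pacing_hz = NULL, l0_px = NULL,
                               smooth = FALSE, search_radius = 12L) {
  roles <- vapply(rois, function(r) r$role, character(1L))
  tails <- rois[roles == "tail"]
  axes <- rois[roles == "axis"]
  if (length(tails) != 2L) abort_input("exactly two tail ROIs are required")
  if (length(axes) != 1L) abort_input("exactly one axis ROI is required")
  axis <- axes[[1L]]$geometry$line
  if (is.null(l0_px)) l0_px <- sqrt(sum((axis[2L, ] - axis[1L, ])^2))

  tr1 <- track_tail(stack, tails[[1L]], axis, search_radius = search_radius)
  tr2 <- track_tail(stack, tails[[2L]], axis, search_radius = search_radius)
  # segment on the stronger tail when pacing is unknown
  seg_src <- if (max(abs(tr1$displacement_px)) >= max(abs(tr2$displacement_px)))
    tr1 else tr2
  beats <- beat_segment(seg_src, pacing_hz)

  md1 <- max_displacement(tr1, beats)
  md2 <- max_displacement(tr2, beats)
  kin <- kinematic_params(tr1, tr2, beats, smooth = smooth)

  pb <- dplyr::full_join(
    dplyr::bind_rows(md1$per_beat %>% dplyr::mutate(tail = 1L),
                     md2$per_beat %>% dplyr::mutate(tail = 2L)),
    kin$per_beat, by = c("beat", "tail")) %>%
    dplyr::arrange(.data$tail, .data$beat)

  structure(list(
    MD1_px = md1$md_mean_px, MD2_px = md2$md_mean_px, L0_px = l0_px,
    FS_percent = fraction_shortening(md1$md_mean_px, md2$md_mean_px, l0_px),
    force_total_px_s2 = kin$force_total_px_s2,
    contractility_px_s = kin$contractility_px_s,
    energy_px2_s2 = kin$energy_px2_s2,
    n_beats = nrow(beats), per_beat = pb,
    traces = list(tail1 = tr1, tail2 = tr2), beats = beats
  ), class = "kinematics_metrics")
}

#' @export
print.kinematics_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<kinematics_metrics> %d beat(s)\n",
           "  MD1 %.3f px  MD2 %.3f px  L0 %.1f px\n",
           "  fraction shortening %.2f %%\n",
           "  force %.2f px/s^2  contractility %.2f px/s  energy %.2f px^2/s^2\n"),
    x$n_beats, x$MD1_px, x$MD2_px, x$L0_px, x$FS_percent,
    x$force_total_px_s2, x$contractility_px_s, x$energy_px2_s2))
  invisible(x)
}
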