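#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a displacement trace
#'
#' @param object a `displacement_trace` from [track_tail()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.displacement_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$displacement_px)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "tail displacement (px)",
                  title = attr(object, "label") %||% NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence trace, optionally with crossing markers
#'
#' @param object a `fluorescence_trace`.
#' @param transients optional tibble from [detect_transitions()] /
#'   [transient_metrics()]; its reference-level crossings are overlaid as
#'   crosses (rise) and circles (fall).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fluorescence_trace <- function(object, transients = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$f_over_f0)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "f/f0") +
    ggplot2::theme_minimal()
  if (!is.null(transients) && nrow(transients) > 0L) {
    marks <- crossing_points(object, transients)
    if (nrow(marks) > 0L)
      p <- p + ggplot2::geom_point(
        data = marks,
        ggplot2::aes(x = .data$time_s, y = .data$f_over_f0,
                     colour = .data$limb, shape = .data$limb), size = 2) +
        ggplot2::scale_shape_manual(values = c(rise = 4, fall = 1)) +
        ggplot2::scale_colour_manual(values = c(rise = "firebrick",
                                                fall = "darkorange"))
  }
  p
}

crossing_points <- function(trace, transients) {
  cross_cols <- grep("^t_[rf]\\d+$", names(transients), value = TRUE)
  purrr::map_dfr(cross_cols, function(cn) {
    ts <- transients[[cn]][!transients$incomplete]
    ts <- ts[is.finite(ts)]
    if (length(ts) == 0L) return(NULL)
    tibble::tibble(time_s = ts,
                   f_over_f0 = stats::approx(trace$time_s, trace$f_over_f0,
                                             xout = ts)$y,
                   limb = if (grepl("^t_r", cn)) "rise" else "fall")
  })
}

#' Stacked beat-to-beat tau bars
#'
#' Horizontal stacked bars, one per retained transient, segmenting the rise
#' (onset to 10/50/90% crossing) or fall (peak to 90/50/10% crossing) into
#' its successive reference-level intervals -- the beat-to-beat variability
#' view of the transient train.
#'
#' @param metrics tibble from [transient_metrics()] (retained rows are
#'   used).
#' @param limb `"fall"` (default) or `"rise"`.
#' @return A ggplot.
#' @export
plot_beat_variability <- function(metrics, limb = c("fall", "rise")) {
  limb <- match.arg(limb)
  keep <- !metrics$incomplete
  if ("outlier" %in% names(metrics)) keep <- keep & !metrics$outlier
  m <- metrics[keep, ]
  if (nrow(m) == 0L) abort_input("no retained transients to plot")
  pct <- attr(metrics, "ref_percents") %||% c(10, 50, 90)
  cols <- if (limb == "rise") paste0("tau_to_peak_", pct)
          else paste0("tau_fall_", rev(pct))
  long <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    taus <- vapply(cols, function(cn) m[[cn]][i], numeric(1L))
    seg <- diff(c(0, taus))  # successive reference-level intervals
    tibble::tibble(transient = m$transient[i],
                   segment = factor(cols, levels = rev(cols)),
                   duration_s = seg)
  })
  long <- long[is.finite(long$duration_s), ]  # crossings the peak never reached
  ggplot2::ggplot(long, ggplot2::aes(x = .data$duration_s,
                                     y = factor(.data$transient),
                                     fill = .data$segment)) +
    ggplot2::geom_col(orientation = "y") +
    ggplot2::labs(x = sprintf("%s time from %s (s)", limb,
                              if (limb == "rise") "onset" else "peak"),
                  y = "transient", fill = NULL) +
    ggplot2::theme_minimal()
}
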