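#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinematics result
#'
#' @param x a `kinematics_metrics` from [analyze_shortening()].
#' @param ... unused.
#' @return The per-tail, per-beat tibble (`tail`, `beat`, `md_px`, peak
#'   speed/acceleration columns).
#' @export
tidy.kinematics_metrics <- function(x, ...) x$per_beat

#' @rdname tidy.kinematics_metrics
#' @return For `glance()`: a one-row tibble of the cell-level read-outs.
#' @export
glance.kinematics_metrics <- function(x, ...) {
  tibble::tibble(MD1_px = x$MD1_px, MD2_px = x$MD2_px, L0_px = x$L0_px,
                 FS_percent = x$FS_percent,
                 force_total_px_s2 = x$force_total_px_s2,
                 contractility_px_s = x$contractility_px_s,
                 energy_px2_s2 = x$energy_px2_s2, n_beats = x$n_beats)
}

#' Tidy a transient summary
#'
#' @param x a `transient_summary` from [summarize_transients()].
#' @param ... unused.
#' @return Per-metric tibble (`metric`, `mean`, `sem`, `n`).
#' @export
tidy.transient_summary <- function(x, ...) x$stats

#' @rdname tidy.transient_summary
#' @return For `glance()`: one row with `F_max` and the transient counts.
#' @export
glance.transient_summary <- function(x, ...) {
  tibble::tibble(F_max = x$F_max, n_transients = x$n_transients,
                 n_retained = x$n_retained, n_outliers = x$n_outliers,
                 n_incomplete = x$n_incomplete)
}

#' @export
tidy.calcium_analysis <- function(x, ...) x$metrics

#' @export
glance.calcium_analysis <- function(x, ...) glance(x$summary)
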