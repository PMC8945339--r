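#' Assemble a trace table
#'
#' A trace table is a tibble whose first column is `time_s` (strictly
#' increasing, constant step) followed by one named column per extracted
#' quantity. It is the common currency the kinematics and calcium modules
#' write and the plotting/statistics layers read.
#'
#' @param time_s time vector in seconds, constant positive step.
#' @param ... named numeric columns, all the same length as `time_s`.
#' @param provenance optional character note (source stack, ROI labels).
#'
#' @return A tibble of class `trace_table`.
#' @export
trace_table <- function(time_s, ..., provenance = NULL) {
  cols <- list(...)
  if (length(cols) == 0L) abort_input("trace_table needs at least one value column")
  if (is.null(names(cols)) || any(names(cols) == ""))
    abort_input("all value columns must be named")
  n <- length(time_s)
  if (n >= 2L) {
    steps <- diff(time_s)
    if (any(steps <= 0) || diff(range(steps)) > 1e-9 * max(steps))
      abort_input("`time_s` must be strictly increasing with a constant step")
  }
  bad <- names(cols)[vapply(cols, length, 1L) != n]
  if (length(bad))
    abort_input(sprintf("column length mismatch: %s", paste(bad, collapse = ", ")))
  out <- tibble::tibble(time_s = as.numeric(time_s), !!!cols)
  attr(out, "provenance") <- provenance
  class(out) <- c("trace_table", class(out))
  out
}

#' Write a trace table to CSV
#'
#' Plain CSV with a header row, `time_s` first, full double precision. `NA`
#' values (e.g. outlier-masked beats) are written as empty cells and re-read
#' as `NA`.
#'
#' @param table a data frame whose first column is `time_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(table, path) {
  if (!is.data.frame(table) || names(table)[1L] != "time_s")
    abort_input("`table` must be a data frame with `time_s` as its first column")
  ok <- tryCatch({
    utils::write.csv(format_full_precision(table), path, row.names = FALSE,
                     quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_input(sprintf("cannot write traces to '%s'", path))
  invisible(path)
}

# format numerics at 17 significant digits so read_traces round-trips exactly
format_full_precision <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- NA_character_
      out
    } else col
  }), check.names = FALSE)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tibble::as_tibble(df)
}
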