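#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, as used for untreated-vs-treated group
#' comparisons. Thin tidy wrapper over [stats::t.test()].
#'
#' @param group_a,group_b numeric vectors, each with at least 2 finite
#'   values.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    abort_input("each group needs at least 2 finite values")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Linear regression with Spearman correlation
#'
#' Ordinary least-squares fit of `y` on `x` with a t-based 95% confidence
#' interval for the slope, reported together with the Spearman rank
#' correlation (average ranks on ties) -- the standard pairing for relating
#' tau, amplitude and shortening read-outs across cells.
#'
#' @param x,y paired numeric vectors, n >= 3 after removing non-finite
#'   pairs.
#' @param conf_level confidence level for the slope interval.
#' @return A one-row tibble: `slope`, `intercept`, `ci_low`, `ci_high`,
#'   `spearman_rho`, `n`.
#' @export
correlate <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort_input("at least 3 complete pairs are required")
  if (stats::var(x) == 0) abort_input("x has zero variance; no slope is defined")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = conf_level)
  rho <- stats::cor(x, y, method = "spearman")
  tibble::tibble(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 ci_low = ci[1L], ci_high = ci[2L],
                 spearman_rho = rho, n = length(x))
}

#' Batch-process many cells from a config file
#'
#' The config (YAML or JSON) lists cells, each with a stack path, an ROI
#' path, a condition label and an analysis kind (`"shortening"` or
#' `"calcium"`). Every cell is analysed independently; failures are logged
#' and skipped. Outputs under `output_dir`: one per-cell trace/metric CSV
#' pair, a pooled `group_table.csv` (one row per cell), a
#' `group_stats.csv` with per-condition mean and SEM for every metric (plus
#' Welch p-values when exactly two conditions are present), and a plain-text
#' `batch.log`.
#'
#' Config keys: `output_dir` (may be overridden by the argument),
#' `frame_interval`, `pacing_hz`, `detrend`, and a list `cells` of
#' `{id, condition, kind, stack, rois}` entries (per-cell `frame_interval`
#' and `pacing_hz` override the top level).
#'
#' @param config path to a YAML/JSON config file, or an equivalent list.
#' @param output_dir overrides the config's `output_dir`.
#' @return Invisibly, a list with `group_table`, `group_stats`,
#'   `output_dir`, `n_failed`.
#' @export
run_batch <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort_input("no output_dir in config or arguments")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "batch.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                                append = TRUE)
  cat(sprintf("myokinet %s batch run\n",
              as.character(utils::packageVersion("myokinet"))),
      file = log_path)
  if (is.null(cfg$cells) || length(cfg$cells) == 0L)
    abort_input("config lists no cells")

  rows <- list()
  n_failed <- 0L
  for (cell in cfg$cells) {
    id <- cell$id %||% "(unnamed)"
    res <- tryCatch(
      process_cell(cell, cfg, out_dir),
      error = function(e) {
        log_line("cell %s FAILED: %s", id, conditionMessage(e))
        warning(sprintf("cell %s skipped: %s", id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      log_line("cell %s (%s, %s) OK", id, cell$condition %||% "?",
               cell$kind %||% "shortening")
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L)
    abort_input(sprintf("all %d cells failed; see %s", n_failed, log_path))

  group_table <- dplyr::bind_rows(rows)
  write_plain_csv(group_table, file.path(out_dir, "group_table.csv"))

  group_stats <- summarize_groups(group_table)
  write_plain_csv(group_stats, file.path(out_dir, "group_stats.csv"))
  log_line("%d cell(s) analysed, %d failed", nrow(group_table), n_failed)

  invisible(list(group_table = group_table, group_stats = group_stats,
                 output_dir = out_dir, n_failed = n_failed))
}

read_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path)
  else
    yaml::read_yaml(path)
}

process_cell <- function(cell, cfg, out_dir) {
  kind <- cell$kind %||% "shortening"
  fi <- cell$frame_interval %||% cfg$frame_interval
  pacing <- cell$pacing_hz %||% cfg$pacing_hz
  stack <- read_stack(cell$stack, frame_interval = fi)
  rois <- read_rois(cell$rois, frame_dim(stack))
  id <- cell$id %||% basename(cell$stack)
  base <- file.path(out_dir, id)
  if (kind == "shortening") {
    m <- analyze_shortening(stack, rois, pacing_hz = pacing,
                            smooth = isTRUE(cfg$smooth))
    tr <- trace_table(m$traces$tail1$time_s,
                      tail1_px = m$traces$tail1$displacement_px,
                      tail2_px = m$traces$tail2$displacement_px)
    write_traces(tr, paste0(base, "_displacement.csv"))
    tibble::tibble(
      id = id, condition = cell$condition %||% "unlabelled", kind = kind,
      MD1_px = m$MD1_px, MD2_px = m$MD2_px, L0_px = m$L0_px,
      FS_percent = m$FS_percent, force_total_px_s2 = m$force_total_px_s2,
      contractility_px_s = m$contractility_px_s,
      energy_px2_s2 = m$energy_px2_s2, n_beats = m$n_beats)
  } else if (kind == "calcium") {
    res <- analyze_calcium(stack, rois, detrend = cfg$detrend %||% "linear",
                           pacing_hz = pacing)
    tr <- trace_table(res$trace$time_s, f_over_f0 = res$trace$f_over_f0)
    write_traces(tr, paste0(base, "_fluorescence.csv"))
    write_plain_csv(res$metrics, paste0(base, "_transients.csv"))
    s <- res$summary
    row <- tibble::tibble(
      id = id, condition = cell$condition %||% "unlabelled", kind = kind,
      F_max = s$F_max, n_transients = s$n_transients,
      n_retained = s$n_retained, n_outliers = s$n_outliers,
      n_incomplete = s$n_incomplete)
    for (i in seq_len(nrow(s$stats)))
      row[[s$stats$metric[i]]] <- s$stats$mean[i]
    row
  } else {
    abort_input(sprintf("cell %s: unknown analysis kind '%s'", id, kind))
  }
}

summarize_groups <- function(group_table) {
  metric_cols <- names(group_table)[vapply(group_table, is.numeric, TRUE)]
  long <- tidyr::pivot_longer(group_table,
                              cols = dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  stats_tbl <- long %>%
    dplyr::group_by(.data$condition, .data$metric) %>%
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sem = sem(.data$value),
                     n = sum(is.finite(.data$value)), .groups = "drop")
  conds <- unique(group_table$condition)
  if (length(conds) == 2L) {
    pvals <- purrr::map_dfr(metric_cols, function(cn) {
      a <- group_table[[cn]][group_table$condition == conds[1L]]
      b <- group_table[[cn]][group_table$condition == conds[2L]]
      p <- tryCatch(welch_t(a, b)$p_value, error = function(e) NA_real_)
      tibble::tibble(metric = cn, welch_p = p)
    })
    stats_tbl <- dplyr::left_join(stats_tbl, pvals, by = "metric")
  }
  stats_tbl
}

write_plain_csv <- function(df, path) {
  utils::write.csv(format_full_precision(df), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
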