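# Per-run and grid-level scan summaries.

#' Summarize one generation run
#'
#' Collapses a run's filter report, fold annotations and escape result into
#' one summary row: valid fraction, number of distinct folds detected,
#' structural hit rate, and sequence escape rate. The escape column follows
#' the supplied `escape_result`; by convention it is computed among
#' structurally assigned sequences (see `escape_denominator`, recorded for
#' provenance). Values are stored at full precision; [format_scan_table()]
#' rounds to 3 decimals for reports.
#'
#' @param filter_report An `fc_filter_report` (from
#'   [apply_filter_pipeline()]).
#' @param annotations An [annotate_folds()] result for the same batch.
#' @param escape_result An [escape_rate()] result for the same batch.
#' @param params List or [sampling_params()] carrying at least `top_k` and
#'   `temperature`.
#' @param escape_denominator `"assigned"` (default) or `"all"`; which query
#'   universe `escape_result` was computed over.
#' @return One-row `data.frame` of class `fc_scan_summary`.
#' @export
summarize_run <- function(filter_report, annotations, escape_result, params,
                          escape_denominator = c("assigned", "all")) {
  escape_denominator <- match.arg(escape_denominator)
  inv <- fold_inventory(annotations)
  out <- data.frame(
    top_k = if (is.null(params$top_k)) NA_integer_ else
      as.integer(params$top_k),
    temperature = as.numeric(params$temperature),
    valid_fraction = attr(filter_report, "valid_fraction"),
    n_folds_detected = inv$n_folds,
    structural_hit_rate = suppressWarnings(structural_hit_rate(annotations)),
    sequence_escape_rate = escape_result$rate,
    stringsAsFactors = FALSE
  )
  attr(out, "escape_denominator") <- escape_denominator
  class(out) <- c("fc_scan_summary", "data.frame")
  out
}

#' Run a hyperparameter-scan summary
#'
#' Produces one summary row per `(temperature, top_k)` grid cell. Cells are
#' supplied by `cell_source`, a function
#' `(temperature, top_k, seed) -> list(filter_report, annotations,
#' escape_result)` that may generate live batches from a token model or load
#' precomputed per-cell hit tables. A cell source returning `NULL` (or
#' raising an error) is skipped with a warning rather than aborting the
#' scan. Rows are ordered top_k-major, temperature-minor; per-cell seeds are
#' derived deterministically from `seed`.
#'
#' @param grid `data.frame` with columns `temperature` and `top_k`.
#' @param cell_source Function as described above.
#' @param seed Integer seed.
#' @param escape_denominator Passed to [summarize_run()].
#' @return `data.frame` of class `fc_scan_table`, one row per completed
#'   cell.
#' @export
run_scan <- function(grid, cell_source, seed = 1L,
                     escape_denominator = "assigned") {
  stopifnot(is.data.frame(grid),
            all(c("temperature", "top_k") %in% names(grid)))
  grid <- grid[order(grid$top_k, grid$temperature), , drop = FALSE]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tk <- grid$top_k[i]; tt <- grid$temperature[i]
    cell <- tryCatch(cell_source(tt, tk, substream_seed(seed, i)),
                     error = function(e) {
                       warning("cell (top_k=", tk, ", T=", tt, ") failed: ",
                               conditionMessage(e))
                       NULL
                     })
    if (is.null(cell)) {
      warning("skipping grid cell (top_k=", tk, ", T=", tt, ")")
      next
    }
    rows[[i]] <- summarize_run(cell$filter_report, cell$annotations,
                               cell$escape_result,
                               params = list(top_k = tk, temperature = tt),
                               escape_denominator = escape_denominator)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(top_k = integer(0), temperature = numeric(0),
                      valid_fraction = numeric(0),
                      n_folds_detected = integer(0),
                      structural_hit_rate = numeric(0),
                      sequence_escape_rate = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("fc_scan_table", "fc_scan_summary", "data.frame")
  out
}

#' Format a scan table for reporting
#'
#' Rounds fractions to 3 decimals (half-up, matching standard report
#' formatting); counts are untouched.
#'
#' @param x An `fc_scan_summary`/`fc_scan_table`.
#' @return A plain `data.frame` of formatted strings and counts.
#' @export
format_scan_table <- function(x) {
  fr <- function(v) sprintf("%.3f", round_half_up(v, 3L))
  data.frame(top_k = x$top_k, temperature = fr(x$temperature),
             valid_fraction = fr(x$valid_fraction),
             n_folds = x$n_folds_detected,
             structural_hit_rate = fr(x$structural_hit_rate),
             sequence_escape_rate = fr(x$sequence_escape_rate),
             stringsAsFactors = FALSE)
}

# Decimal rounding with exact half-up ties, as report tables expect.
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' @export
print.fc_scan_summary <- function(x, ...) {
  print.data.frame(format_scan_table(x), row.names = FALSE)
  invisible(x)
}

#' Write a scan table as TSV
#'
#' @param x An `fc_scan_table`.
#' @param path Output file.
#' @export
write_scan_table <- function(x, path) {
  write_tsv_hash(format_scan_table(x), path)
  invisible(path)
}

#' Inverse-folding batch bookkeeping
#'
#' Number of sequence-design jobs when sampling `per_template` sequences
#' from each of `n_templates` backbone templates.
#'
#' @param n_templates,per_template Non-negative counts.
#' @return `n_templates * per_template`.
#' @export
plan_inverse_folding_batch <- function(n_templates, per_template) {
  n_templates <- as.numeric(n_templates)
  per_template <- as.numeric(per_template)
  if (is.na(n_templates) || is.na(per_template) ||
      n_templates < 0 || per_template < 0) {
    stop("counts must be non-negative")
  }
  n_templates * per_template
}
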