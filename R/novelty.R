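# Sequence-escape statistics from homology-search hit tables.

M8_COLUMNS <- c("query", "target", "pident", "alnlen", "mismatch", "gapopen",
                "qstart", "qend", "tstart", "tend", "evalue", "bits")

#' Parse a BLAST-m8 / MMseqs2 homology hit table
#'
#' Reads the 12-column tab-separated alignment format shared by BLAST and
#' MMseqs2 (at least 11 columns required; the E-value is column 11). Rows
#' with a non-numeric E-value are rejected with a warning; a negative
#' E-value is a hard parse error.
#'
#' @param path m8 file; lines starting with `#` are ignored.
#' @return A `data.frame` of hits with standard m8 column names (`query`,
#'   `target`, ..., `evalue`, and `bits` when present).
#' @export
parse_homology_hits <- function(path) {
  raw <- read_tsv_table(path, min_cols = 11L)
  if (nrow(raw) == 0L) {
    return(data.frame(query = character(0), target = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  ncols <- min(ncol(raw), 12L)
  hits <- raw[, seq_len(ncols), drop = FALSE]
  names(hits) <- M8_COLUMNS[seq_len(ncols)]
  hits$query <- as.character(hits$query)
  hits$target <- as.character(hits$target)
  ev <- suppressWarnings(as.numeric(hits$evalue))
  bad <- is.na(ev)
  if (any(bad)) {
    warning("rejected ", sum(bad),
            " homology row(s) with malformed E-value at line(s): ",
            paste(utils::head(which(bad), 20L), collapse = ", "))
    hits <- hits[!bad, , drop = FALSE]
    ev <- ev[!bad]
  }
  if (any(ev < 0)) {
    stop("negative E-value at data row(s): ",
         paste(utils::head(which(ev < 0), 10L), collapse = ", "))
  }
  hits$evalue <- ev
  rownames(hits) <- NULL
  hits
}

#' Sequence escape rate
#'
#' A query "escapes" when it returns no homology hit of any length at the
#' E-value cutoff. Because search tools omit no-hit queries from tabular
#' output, the query universe must be supplied independently of the hit
#' file; queries absent from `hits` count as escaped.
#'
#' @param query_ids Character vector: the full (non-empty) query universe.
#' @param hits Homology-hit `data.frame` (columns `query`, `evalue`).
#' @param evalue_max E-value cutoff (default 0.01).
#' @param inclusive If `TRUE` (default) a hit qualifies at
#'   `evalue <= evalue_max`; if `FALSE` the comparison is strict.
#' @return List with `rate` (escaped / total), `escaped` (id vector),
#'   `n_total`, `n_escaped`, and the cutoff settings echoed.
#' @export
escape_rate <- function(query_ids, hits, evalue_max = 0.01,
                        inclusive = TRUE) {
  query_ids <- unique(as.character(query_ids))
  if (length(query_ids) == 0L) stop("query_ids must be non-empty")
  unknown <- setdiff(unique(hits$query), query_ids)
  if (length(unknown)) {
    warning("ignoring hits for ", length(unknown),
            " query id(s) absent from the query universe")
  }
  qual <- if (inclusive) hits$evalue <= evalue_max else hits$evalue < evalue_max
  hit_ids <- unique(hits$query[qual])
  escaped <- setdiff(query_ids, hit_ids)
  list(rate = length(escaped) / length(query_ids),
       escaped = escaped,
       n_total = length(query_ids),
       n_escaped = length(escaped),
       evalue_max = evalue_max,
       inclusive = inclusive)
}

#' Escape rate per assigned fold
#'
#' Restricts [escape_rate()] to the queries assigned each fold; folds with
#' no assigned queries are omitted.
#'
#' @param annotations An [annotate_folds()] result.
#' @param hits Homology-hit `data.frame`.
#' @param evalue_max,inclusive As in [escape_rate()].
#' @return `data.frame` with columns `fold`, `n_assigned`, `n_escaped`,
#'   `escape_rate`.
#' @export
per_fold_escape <- function(annotations, hits, evalue_max = 0.01,
                            inclusive = TRUE) {
  assigned <- annotations[!is.na(annotations$fold), , drop = FALSE]
  folds <- sort(unique(assigned$fold))
  rows <- lapply(folds, function(f) {
    ids <- assigned$query_id[assigned$fold == f]
    er <- suppressWarnings(
      escape_rate(ids, hits, evalue_max = evalue_max, inclusive = inclusive))
    data.frame(fold = f, n_assigned = er$n_total, n_escaped = er$n_escaped,
               escape_rate = er$rate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fold = character(0), n_assigned = integer(0),
                      n_escaped = integer(0), escape_rate = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}
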