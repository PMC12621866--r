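# Validity, truncation, composition and deduplication filters.

#' Sequence filter configuration
#'
#' @param forbidden_letters Rare/ambiguous one-letter codes that invalidate a
#'   sequence (default B, J, O, U, X, Z).
#' @param max_length Truncation length in residues (default 100).
#' @param max_single_aa_fraction Composition cap: sequences in which any one
#'   amino acid strictly exceeds this fraction fail the composition filter
#'   (default 0.20; used for structure-validation sets, not generated
#'   batches).
#' @param min_length Minimum length for validation-set filtering (default
#'   21, i.e. sequences of 20 residues or fewer are dropped).
#' @param max_resolution_angstrom Maximum crystallographic resolution for
#'   validation-set filtering, in Angstrom (default 9); consumed from
#'   metadata supplied alongside sequences.
#' @return An object of class `fc_filter_config`.
#' @export
filter_config <- function(forbidden_letters = FORBIDDEN_LETTERS,
                          max_length = 100L,
                          max_single_aa_fraction = 0.20,
                          min_length = 21L,
                          max_resolution_angstrom = 9) {
  stopifnot(max_length >= 1, min_length >= 1, max_resolution_angstrom > 0,
            max_single_aa_fraction > 0, max_single_aa_fraction <= 1)
  forbidden_letters <- unique(toupper(as.character(forbidden_letters)))
  structure(list(forbidden_letters = forbidden_letters,
                 max_length = as.integer(max_length),
                 max_single_aa_fraction = max_single_aa_fraction,
                 min_length = as.integer(min_length),
                 max_resolution_angstrom = max_resolution_angstrom),
            class = "fc_filter_config")
}

#' Validity check for a residue string
#'
#' A sequence is invalid if it is empty or contains any forbidden
#' (rare/ambiguous) letter.
#'
#' @param seq Uppercase residue string.
#' @param config A [filter_config()].
#' @return A list with `valid` (logical) and `reason` (`NA` if valid; the
#'   first offending letter or `"empty"` otherwise).
#' @export
is_valid_sequence <- function(seq, config = filter_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[a-z[:space:]]", seq)) {
    stop("sequence must be pre-cleaned: uppercase, no whitespace")
  }
  if (!nzchar(seq)) {
    return(list(valid = FALSE, reason = "empty"))
  }
  chars <- strsplit(seq, "")[[1L]]
  hit <- match(TRUE, chars %in% config$forbidden_letters)
  if (!is.na(hit)) {
    return(list(valid = FALSE, reason = chars[hit]))
  }
  list(valid = TRUE, reason = NA_character_)
}

# Vectorized validity used by the pipeline.
valid_mask <- function(seqs, config) {
  pattern <- paste0("[", paste(config$forbidden_letters, collapse = ""), "]")
  nzchar(seqs) & !grepl(pattern, seqs)
}

#' Truncate a sequence to a maximum length
#'
#' @param seq Residue string (vectorized).
#' @param max_length Positive integer.
#' @return Prefix of length `min(nchar(seq), max_length)`.
#' @export
truncate_sequence <- function(seq, max_length = 100L) {
  stopifnot(max_length >= 1)
  substr(seq, 1L, as.integer(max_length))
}

#' Single-residue composition filter
#'
#' Fails a sequence in which any one amino acid strictly exceeds
#' `max_fraction` of the residues (e.g. 21 alanines in a 100-mer fail at the
#' default 0.20; exactly 20 pass).
#'
#' @param seq Non-empty residue string.
#' @param max_fraction Fraction in (0, 1].
#' @return `TRUE` if the sequence passes.
#' @export
composition_filter <- function(seq, max_fraction = 0.20) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("composition_filter: empty sequence")
  counts <- table(strsplit(seq, "")[[1L]])
  max(counts) / nchar(seq) <= max_fraction
}

#' Exact-sequence deduplication
#'
#' Removes records whose residue sequence has appeared earlier in the batch;
#' the first occurrence is kept and input order is otherwise preserved.
#'
#' @param records Sequence-record `data.frame` (column `sequence`).
#' @return List with `records` (survivors) and `removed` (count).
#' @export
deduplicate <- function(records) {
  keep <- !duplicated(records$sequence)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, removed = sum(!keep))
}

#' Apply the standard filter pipeline
#'
#' Stages, in order: truncation to `config$max_length`, validity
#' (empty/forbidden-letter) filtering, optional composition filtering, and
#' optional exact deduplication. Truncation precedes validity, so a
#' forbidden letter beyond the truncation point does not invalidate a
#' sequence.
#'
#' @param records Sequence-record `data.frame`.
#' @param config A [filter_config()].
#' @param dedup Apply exact deduplication (default `TRUE`).
#' @param composition Apply the single-residue composition filter (default
#'   `FALSE`; a validation-set rule).
#' @return List with `records` (survivors) and `report`, an
#'   `fc_filter_report` data.frame of per-stage `n_in`/`n_out`/`n_removed`
#'   counts carrying `valid_fraction` (valid / batch input) as an attribute.
#' @export
apply_filter_pipeline <- function(records, config = filter_config(),
                                  dedup = TRUE, composition = FALSE) {
  stages <- character(0); n_in <- integer(0); n_out <- integer(0)
  add_stage <- function(name, nin, nout) {
    stages <<- c(stages, name); n_in <<- c(n_in, nin); n_out <<- c(n_out, nout)
  }
  n0 <- nrow(records)

  records$sequence <- truncate_sequence(records$sequence, config$max_length)
  add_stage("truncate", n0, n0)

  ok <- valid_mask(records$sequence, config)
  records <- records[ok, , drop = FALSE]
  add_stage("validity", n0, nrow(records))
  n_valid <- nrow(records)

  if (composition) {
    nin <- nrow(records)
    ok <- vapply(records$sequence, composition_filter, logical(1),
                 max_fraction = config$max_single_aa_fraction,
                 USE.NAMES = FALSE)
    records <- records[ok, , drop = FALSE]
    add_stage("composition", nin, nrow(records))
  }

  if (dedup) {
    nin <- nrow(records)
    dd <- deduplicate(records)
    records <- dd$records
    add_stage("dedup", nin, nrow(records))
  }

  rownames(records) <- NULL
  report <- data.frame(stage = stages, n_in = n_in, n_out = n_out,
                       n_removed = n_in - n_out, stringsAsFactors = FALSE)
  attr(report, "valid_fraction") <- if (n0 > 0) n_valid / n0 else 0
  class(report) <- c("fc_filter_report", "data.frame")
  list(records = records, report = report)
}

#' @export
print.fc_filter_report <- function(x, ...) {
  cat("<filter report> valid fraction:",
      format(attr(x, "valid_fraction"), digits = 4), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report An `fc_filter_report`.
#' @param path Output file.
#' @export
write_filter_report <- function(report, path) {
  write_tsv_hash(as.data.frame(report), path)
  invisible(path)
}
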