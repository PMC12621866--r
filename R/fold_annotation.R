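# Consensus SCOP fold assignment from structure-search hit tables.

#' Annotation thresholds
#'
#' @param tm_min TM-score threshold; hits must satisfy `tm_score > tm_min`
#'   strictly (default 0.5, the conventional shared-fold cutoff).
#' @param cov_min Coverage threshold; strict (default 0.8).
#' @param coverage_rule `"max_of_two"` (consensus assignment:
#'   `max(query_coverage, target_coverage) > cov_min`) or `"both"` (both
#'   coverages must pass; the rule used when building reciprocal
#'   sequence-structure databases).
#' @return An object of class `fc_annotation_config`.
#' @export
annotation_config <- function(tm_min = 0.5, cov_min = 0.8,
                              coverage_rule = c("max_of_two", "both")) {
  stopifnot(tm_min > 0, tm_min < 1, cov_min > 0, cov_min < 1)
  coverage_rule <- match.arg(coverage_rule)
  structure(list(tm_min = tm_min, cov_min = cov_min,
                 coverage_rule = coverage_rule),
            class = "fc_annotation_config")
}

#' Parse a structure-search hit table
#'
#' Reads a Foldseek-style tab-separated hit table. The default column map
#' corresponds to a search formatted as
#' `query,target,alntmscore,qcov,tcov`. Rows with malformed numeric fields
#' or scores outside `[0, 1]` are rejected with a warning citing their data
#' row numbers (1-based, comment lines excluded).
#'
#' @param path TSV file; lines starting with `#` are ignored.
#' @param column_spec Named integer vector mapping the fields `query`,
#'   `target`, `tm_score`, `query_coverage`, `target_coverage` to column
#'   positions.
#' @return A `data.frame` of validated hits with those five columns.
#' @export
parse_structure_hits <- function(path,
                                 column_spec = c(query = 1L, target = 2L,
                                                 tm_score = 3L,
                                                 query_coverage = 4L,
                                                 target_coverage = 5L)) {
  required <- c("query", "target", "tm_score", "query_coverage",
                "target_coverage")
  if (!all(required %in% names(column_spec))) {
    stop("column_spec must name: ", paste(required, collapse = ", "))
  }
  raw <- read_tsv_table(path, min_cols = max(column_spec))
  if (nrow(raw) == 0L) {
    warning("no hit rows in ", path)
    return(empty_structure_hits())
  }
  hits <- data.frame(
    query = as.character(raw[[column_spec[["query"]]]]),
    target = as.character(raw[[column_spec[["target"]]]]),
    tm_score = suppressWarnings(as.numeric(raw[[column_spec[["tm_score"]]]])),
    query_coverage = suppressWarnings(
      as.numeric(raw[[column_spec[["query_coverage"]]]])),
    target_coverage = suppressWarnings(
      as.numeric(raw[[column_spec[["target_coverage"]]]])),
    stringsAsFactors = FALSE
  )
  num <- c("tm_score", "query_coverage", "target_coverage")
  bad <- rowSums(is.na(hits[num])) > 0 |
    rowSums(hits[num] < 0, na.rm = TRUE) > 0 |
    rowSums(hits[num] > 1, na.rm = TRUE) > 0 |
    !nzchar(hits$query) | !nzchar(hits$target)
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed hit row(s) at line(s): ",
            paste(utils::head(which(bad), 20L), collapse = ", "))
    hits <- hits[!bad, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

empty_structure_hits <- function() {
  data.frame(query = character(0), target = character(0),
             tm_score = numeric(0), query_coverage = numeric(0),
             target_coverage = numeric(0), stringsAsFactors = FALSE)
}

# Normalize a fold map (data.frame or named vector) to a named character
# vector target_id -> fold_id, validating the "x.N" label pattern.
as_fold_map <- function(fold_map) {
  if (is.data.frame(fold_map)) {
    stopifnot(ncol(fold_map) >= 2)
    fm <- stats::setNames(as.character(fold_map[[2L]]),
                          as.character(fold_map[[1L]]))
  } else {
    fm <- fold_map
  }
  if (is.null(names(fm))) stop("fold_map must be named by target id")
  bad <- !grepl("^[a-z]\\.[0-9]+$", fm)
  if (any(bad)) {
    stop("fold ids must look like 'a.4'; offending: ",
         paste(utils::head(unique(fm[bad]), 5L), collapse = ", "))
  }
  fm
}

# Hits surviving the threshold rule.
passing_hits <- function(hits, config) {
  cov <- switch(config$coverage_rule,
                max_of_two = pmax(hits$query_coverage, hits$target_coverage),
                both = pmin(hits$query_coverage, hits$target_coverage))
  hits[hits$tm_score > config$tm_min & cov > config$cov_min, , drop = FALSE]
}

#' Consensus fold assignment for one query
#'
#' Hits failing `tm_score > tm_min` or the coverage rule (strict
#' inequalities) are discarded; surviving hits vote for the fold of their
#' target via `fold_map`, one vote per hit row. The plurality fold wins.
#' Plurality ties are broken by the highest `tm_score` among each tied
#' fold's hits, then by lexicographic fold id; broken ties are flagged.
#'
#' @param hits `data.frame` of structure hits, all sharing one `query` id.
#' @param fold_map Mapping `target_id -> fold_id` (named character vector or
#'   two-column `data.frame`).
#' @param config An [annotation_config()].
#' @return List with `query_id`, `assigned_fold` (`NA` if no hit survives),
#'   `vote_counts` (named integer), `n_hits_pass` and `tie_broken`.
#' @export
assign_consensus_fold <- function(hits, fold_map,
                                  config = annotation_config()) {
  fm <- as_fold_map(fold_map)
  qid <- unique(hits$query)
  if (length(qid) > 1L) stop("hits span multiple queries: ",
                             paste(qid, collapse = ", "))
  if (length(qid) == 0L) qid <- NA_character_
  surv <- passing_hits(hits, config)
  if (nrow(surv) == 0L) {
    return(list(query_id = qid, assigned_fold = NA_character_,
                vote_counts = integer(0), n_hits_pass = 0L,
                tie_broken = FALSE))
  }
  missing <- setdiff(unique(surv$target), names(fm))
  if (length(missing)) {
    stop("targets absent from fold_map: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  folds <- unname(fm[surv$target])
  cv <- consensus_vote(folds, surv$tm_score)
  votes <- sort(table(folds), decreasing = TRUE)
  list(query_id = qid, assigned_fold = cv$fold,
       vote_counts = stats::setNames(as.integer(votes), names(votes)),
       n_hits_pass = nrow(surv), tie_broken = cv$tie_broken)
}

# Plurality vote with the deterministic tie rule: most hits, then highest
# max tm_score within the tied folds, then lexicographic fold id.
consensus_vote <- function(folds, tm_scores) {
  votes <- table(folds)
  vmax <- max(votes)
  top <- names(votes)[votes == vmax]
  tie_broken <- length(top) > 1L
  if (tie_broken) {
    best_tm <- vapply(top, function(f) max(tm_scores[folds == f]), numeric(1))
    top <- top[best_tm == max(best_tm)]
    top <- sort(top)[1L]            # lexicographic fallback
  }
  list(fold = top[1L], votes = as.integer(vmax), tie_broken = tie_broken)
}

#' Batch consensus annotation
#'
#' Applies [assign_consensus_fold()] per query. Queries listed in
#' `query_ids` but absent from the hit table are annotated `NA` (no fold),
#' not treated as errors.
#'
#' @param hits Structure-hit `data.frame` (possibly many queries).
#' @param fold_map Mapping `target_id -> fold_id`.
#' @param config An [annotation_config()].
#' @param query_ids Full query universe; defaults to the queries present in
#'   `hits`.
#' @return A `data.frame` of class `fc_fold_annotations` with one row per
#'   query: `query_id`, `fold` (`NA` when unassigned), `class` (fold-id
#'   prefix, e.g. `"a"`), `votes` (winning fold's hit count), `n_hits_pass`,
#'   `tie_broken`.
#' @export
annotate_folds <- function(hits, fold_map, config = annotation_config(),
                           query_ids = NULL) {
  fm <- as_fold_map(fold_map)
  if (is.null(query_ids)) query_ids <- unique(hits$query)
  nq <- length(query_ids)
  surv <- passing_hits(hits, config)
  missing <- setdiff(unique(surv$target), names(fm))
  if (length(missing)) {
    stop("targets absent from fold_map: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  folds_all <- unname(fm[surv$target])
  rows_by_q <- split(seq_len(nrow(surv)),
                     factor(surv$query, levels = query_ids))
  fold <- rep(NA_character_, nq)
  votes <- integer(nq)
  n_pass <- lengths(rows_by_q)
  tie <- logical(nq)
  for (i in which(n_pass > 0L)) {
    r <- rows_by_q[[i]]
    cv <- consensus_vote(folds_all[r], surv$tm_score[r])
    fold[i] <- cv$fold
    votes[i] <- cv$votes
    tie[i] <- cv$tie_broken
  }
  out <- data.frame(query_id = query_ids, fold = fold,
                    class = ifelse(is.na(fold), NA_character_,
                                   sub("\\..*$", "", fold)),
                    votes = votes, n_hits_pass = unname(n_pass),
                    tie_broken = tie, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fc_fold_annotations", "data.frame")
  out
}

#' Structural hit rate
#'
#' Fraction of queries assignable to any fold label by the consensus rule.
#'
#' @param annotations An [annotate_folds()] result.
#' @return Fraction in `[0, 1]`; 0 (with a warning) for empty input.
#' @export
structural_hit_rate <- function(annotations) {
  if (nrow(annotations) == 0L) {
    warning("no annotations; structural hit rate reported as 0")
    return(0)
  }
  mean(!is.na(annotations$fold))
}

#' Fold inventory and coverage
#'
#' @param annotations An [annotate_folds()] result.
#' @param reference_total Size of the reference fold universe (default 1579
#'   SCOP fold labels).
#' @return List with `n_folds` (distinct assigned folds), `counts` (named
#'   per-fold assignment counts) and `coverage` (`n_folds /
#'   reference_total`).
#' @export
fold_inventory <- function(annotations, reference_total = 1579L) {
  assigned <- annotations$fold[!is.na(annotations$fold)]
  counts <- sort(table(assigned), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(n_folds = length(counts), counts = counts,
       coverage = length(counts) / reference_total)
}

#' Topology (SCOP class) distribution of assigned queries
#'
#' Classes are the fold-id prefixes: `a` (all-alpha), `b` (all-beta), `c`
#' (alpha/beta), `d` (alpha+beta), etc.
#'
#' @param annotations An [annotate_folds()] result.
#' @return Named fractions over assigned queries, summing to 1.
#' @export
topology_distribution <- function(annotations) {
  cls <- annotations$class[!is.na(annotations$fold)]
  if (length(cls) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(cls)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Per-fold enrichment of generated vs natural counts
#'
#' Log2 ratio of add-one-smoothed fold frequencies:
#' `log2((g_f + 1) / (G + K)) - log2((n_f + 1) / (N + K))` with `K` the fold
#' universe size and `G`, `N` the total counts. Antisymmetric under swapping
#' the two count maps.
#'
#' @param generated_counts,natural_counts Named integer vectors of per-fold
#'   assignment counts over a shared fold universe (missing folds count 0).
#' @return Named numeric vector of per-fold log2 enrichments.
#' @export
fold_enrichment <- function(generated_counts, natural_counts) {
  universe <- union(names(generated_counts), names(natural_counts))
  if (length(universe) == 0L) stop("empty fold universe")
  g <- stats::setNames(rep(0, length(universe)), universe)
  n <- g
  g[names(generated_counts)] <- generated_counts
  n[names(natural_counts)] <- natural_counts
  K <- length(universe)
  log2((g + 1) / (sum(g) + K)) - log2((n + 1) / (sum(n) + K))
}

#' Reciprocal hit filtering
#'
#' Retains unordered pairs present in both search directions, each direction
#' passing `tm_score > tm_min` and both coverages `> cov_min` (note: both
#' coverages, unlike consensus assignment). Exact duplicate pairs are
#' collapsed.
#'
#' @param hits_ab,hits_ba Structure-hit `data.frame`s with swapped
#'   query/target roles.
#' @param config An [annotation_config()]; its `coverage_rule` is forced to
#'   `"both"`.
#' @return `data.frame` with columns `id_a`, `id_b` (the A-side and B-side
#'   ids of each reciprocal pair).
#' @export
reciprocal_filter <- function(hits_ab, hits_ba,
                              config = annotation_config(coverage_rule = "both")) {
  config$coverage_rule <- "both"
  ab <- passing_hits(hits_ab, config)
  ba <- passing_hits(hits_ba, config)
  key_ab <- paste(ab$query, ab$target, sep = "\r")
  key_ba <- paste(ba$target, ba$query, sep = "\r")   # swap roles back
  keep <- unique(key_ab[key_ab %in% key_ba])
  if (length(keep) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keep, "\r", fixed = TRUE)
  data.frame(id_a = vapply(parts, `[[`, "", 1L),
             id_b = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Write fold annotations as TSV
#'
#' @param annotations An [annotate_folds()] result.
#' @param path Output file.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv_hash(as.data.frame(annotations), path)
  invisible(path)
}
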