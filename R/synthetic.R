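# Synthetic inputs with planted ground truth: toy token models, hit tables,
# toy coordinate sets. Every pipeline stage is testable against these
# without GPU inference or external databases.

#' Toy Markov token model
#'
#' Small vocabularies (at most 8 tokens including STOP) with exactly known
#' transition probabilities, supporting both the autoregressive and the
#' masked contracts. Structures:
#' \describe{
#'   \item{uniform}{every conditional is uniform over the vocabulary.}
#'   \item{chain}{deterministic cycle ending in STOP; exactly one output
#'     sequence, with probability 1.}
#'   \item{two_mode}{two high-probability self-repeating sequence families,
#'     so temperature effects on mode concentration are observable.}
#'   \item{random}{seeded random start/transition rows (all strictly
#'     positive).}
#' }
#' The masked conditional for a position equals the autoregressive
#' conditional on its left neighbour (the toy ignores the masked right
#' context).
#'
#' @param n_tokens Total vocabulary size including STOP (2..8).
#' @param structure One of `"uniform"`, `"two_mode"`, `"chain"`, `"random"`.
#' @param seed Seed for the `"random"` structure (ignored otherwise).
#' @return A [token_model()] with both modes.
#' @export
make_toy_markov_model <- function(n_tokens = 3L,
                                  structure = c("uniform", "two_mode",
                                                "chain", "random"),
                                  seed = 1L) {
  structure_kind <- match.arg(structure)
  n_tokens <- as.integer(n_tokens)
  if (n_tokens < 2L || n_tokens > 8L) stop("n_tokens must be in 2..8")
  toks <- c(AA_ALPHABET[seq_len(n_tokens - 1L)], "<stop>")
  vocab <- vocabulary(toks, stop_index = n_tokens)
  nr <- n_tokens - 1L                       # residue tokens
  start <- numeric(n_tokens)
  P <- matrix(0, nrow = nr, ncol = n_tokens)  # row: last token; col: next
  if (structure_kind == "uniform") {
    start[] <- 1 / n_tokens
    P[] <- 1 / n_tokens
  } else if (structure_kind == "chain") {
    start[1L] <- 1
    for (i in seq_len(nr)) {
      P[i, if (i < nr) i + 1L else n_tokens] <- 1
    }
  } else if (structure_kind == "two_mode") {
    if (nr < 2L) stop("two_mode needs at least 2 residue tokens")
    start[1L] <- 0.55; start[2L] <- 0.35; start[n_tokens] <- 0.05
    if (nr > 2L) start[3:nr] <- 0.05 / (nr - 2L)
    start <- start / sum(start)
    for (i in seq_len(nr)) {
      P[i, ] <- 0.15 / (n_tokens - 2L)      # spread over non-self tokens
      P[i, i] <- 0.75
      P[i, n_tokens] <- 0.10
      P[i, ] <- P[i, ] / sum(P[i, ])
    }
  } else {                                   # random
    set.seed(substream_seed(seed, 7L))
    start <- stats::runif(n_tokens, 0.05, 1)
    start <- start / sum(start)
    for (i in seq_len(nr)) {
      p <- stats::runif(n_tokens, 0.05, 1)
      P[i, ] <- p / sum(p)
    }
  }
  next_fn <- function(context) {
    if (length(context) == 0L) start else P[context[length(context)], ]
  }
  masked_fn <- function(filled, position, length) {
    if (length(filled) == 0L) start else P[filled[length(filled)], ]
  }
  token_model(vocab, next_fn, masked_fn,
              name = paste0("toy_markov_", structure_kind))
}

#' Planted synthetic batch specification
#'
#' Defines the ground truth of a synthetic batch: how many sequences, what
#' fraction carry a forbidden letter, how many of the valid ones are
#' structurally assignable across how many distinct folds, and what
#' fraction of the assignable ones escape homology detection. All realized
#' counts are exact by deterministic rounding, never sampled, so
#' counts-based statistics are recovered exactly.
#'
#' @param n_sequences Batch size.
#' @param invalid_fraction Fraction of sequences planted with one `X`.
#' @param assigned_fraction Fraction of valid sequences given passing
#'   structure hits.
#' @param n_distinct_folds Number of distinct planted folds (each receives
#'   at least one query).
#' @param fold_weights Optional relative weights over the planted folds
#'   (default equal); realized per-fold counts use largest-remainder
#'   rounding.
#' @param escape_fraction_among_assigned Fraction of assigned queries with
#'   no qualifying homology hit.
#' @param seed Integer seed.
#' @param seq_length Residue length of the planted sequences (default 100).
#' @param reference_fold_total Fold universe size used for coverage
#'   statistics (default 1579).
#' @return An object of class `fc_planted_spec`.
#' @export
planted_batch_spec <- function(n_sequences, invalid_fraction = 0,
                               assigned_fraction = 0.3,
                               n_distinct_folds = 10L,
                               fold_weights = NULL,
                               escape_fraction_among_assigned = 0.5,
                               seed = 1L, seq_length = 100L,
                               reference_fold_total = 1579L) {
  stopifnot(n_sequences >= 1,
            invalid_fraction >= 0, invalid_fraction <= 1,
            assigned_fraction >= 0, assigned_fraction <= 1,
            escape_fraction_among_assigned >= 0,
            escape_fraction_among_assigned <= 1,
            n_distinct_folds >= 0,
            n_distinct_folds <= reference_fold_total)
  if (!is.null(fold_weights)) {
    stopifnot(length(fold_weights) == n_distinct_folds, all(fold_weights > 0))
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 invalid_fraction = invalid_fraction,
                 assigned_fraction = assigned_fraction,
                 n_distinct_folds = as.integer(n_distinct_folds),
                 fold_weights = fold_weights,
                 escape_fraction_among_assigned =
                   escape_fraction_among_assigned,
                 seed = as.integer(seed),
                 seq_length = as.integer(seq_length),
                 reference_fold_total = as.integer(reference_fold_total)),
            class = "fc_planted_spec")
}

# Largest-remainder apportionment of `total` into length(weights) positive
# parts proportional to weights (each part >= 1 when total >= k).
apportion <- function(total, weights) {
  k <- length(weights)
  if (k == 0L) return(integer(0))
  if (total < k) stop("cannot give each of ", k, " folds at least one of ",
                      total, " queries")
  w <- weights / sum(weights)
  base <- pmax(1, floor(total * w))
  # shrink if the >=1 floor overshot
  while (sum(base) > total) {
    i <- which.max(base)
    base[i] <- base[i] - 1L
  }
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- total * w - floor(total * w)
    ord <- order(frac, decreasing = TRUE)
    add <- ord[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

# The planted fold universe: cycle classes a..d through fold numbers.
planted_fold_ids <- function(k) {
  if (k == 0L) return(character(0))
  cls <- c("a", "b", "c", "d")
  i <- seq_len(k) - 1L
  paste0(cls[i %% 4L + 1L], ".", i %/% 4L + 1L)
}

#' Synthetic hit tables with planted ground truth
#'
#' Generates a full set of pipeline inputs for one batch: sequence records
#' (background-model draws; planted-invalid ones carry one `X` at a random
#' position), a structure-search hit table in which exactly the planted
#' assignable queries receive threshold-passing hits voting their planted
#' fold (plus sub-threshold decoy hits), a fold map covering every
#' referenced target, a homology hit table in which exactly the planted
#' escapees lack a qualifying hit (non-escapees get one at E = 1e-5,
#' escapees a decoy at E = 0.5), and the truth record of every planted
#' value.
#'
#' @param spec A [planted_batch_spec()].
#' @param outdir Optional directory; when given, writes `sequences.fasta`,
#'   `structure_hits.tsv`, `homology_hits.m8`, `fold_map.tsv` and
#'   `truth.json` there.
#' @return List with `records`, `structure_hits`, `homology_hits`,
#'   `fold_map` (two-column `data.frame`), and `truth` (planted counts and
#'   fractions).
#' @export
make_synthetic_hit_tables <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "fc_planted_spec"))
  set.seed(substream_seed(spec$seed, 11L))
  n <- spec$n_sequences
  ids <- sprintf("q%07d", seq_len(n))

  bg <- background_model(length = spec$seq_length)
  records <- generate_background(bg, n, seed = spec$seed)
  records$id <- ids
  records$source <- "synthetic_planted"

  n_invalid <- round(spec$invalid_fraction * n)
  if (n_invalid > 0) {
    inv_rows <- seq(n - n_invalid + 1L, n)
    pos <- sample.int(spec$seq_length, n_invalid, replace = TRUE)
    records$sequence[inv_rows] <- mapply(function(s, p) {
      substr(s, p, p) <- "X"; s
    }, records$sequence[inv_rows], pos, USE.NAMES = FALSE)
  }
  valid_ids <- ids[seq_len(n - n_invalid)]
  n_valid <- length(valid_ids)

  n_assigned <- round(spec$assigned_fraction * n_valid)
  k <- spec$n_distinct_folds
  if (n_assigned > 0 && k == 0L) {
    stop("assigned queries require n_distinct_folds >= 1")
  }
  folds <- planted_fold_ids(k)
  fold_counts <- if (n_assigned > 0) {
    apportion(n_assigned,
              if (is.null(spec$fold_weights)) rep(1, k) else spec$fold_weights)
  } else integer(k)
  assigned_ids <- valid_ids[seq_len(n_assigned)]
  assigned_fold <- rep(folds, fold_counts)

  # structure hits: 1-3 passing hits voting the planted fold, plus an
  # occasional sub-threshold decoy to a different fold
  decoy_fold <- "z.999"
  sh <- list()
  if (n_assigned > 0) {
    n_pass <- sample(1:3, n_assigned, replace = TRUE)
    qi <- rep.int(seq_len(n_assigned), n_pass)
    m <- length(qi)
    sh[["pass"]] <- data.frame(
      query = assigned_ids[qi],
      target = paste0("d_", assigned_fold[qi], "_",
                      stats::ave(qi, qi, FUN = seq_along)),
      tm_score = stats::runif(m, 0.55, 0.95),
      query_coverage = stats::runif(m, 0.85, 0.99),
      target_coverage = stats::runif(m, 0.40, 0.99),
      stringsAsFactors = FALSE)
    decoy <- which(stats::runif(n_assigned) < 0.3)
    if (length(decoy)) {
      sh[["decoy"]] <- data.frame(
        query = assigned_ids[decoy],
        target = paste0("decoy_", seq_along(decoy)),
        tm_score = stats::runif(length(decoy), 0.05, 0.45),
        query_coverage = stats::runif(length(decoy), 0.85, 0.99),
        target_coverage = stats::runif(length(decoy), 0.40, 0.99),
        stringsAsFactors = FALSE)
    }
  }
  # some unassigned queries get sub-threshold rows only
  unassigned_ids <- setdiff(valid_ids, assigned_ids)
  if (length(unassigned_ids)) {
    nd <- max(1L, round(0.2 * length(unassigned_ids)))
    pick <- unassigned_ids[seq_len(nd)]
    sh[["unassigned_decoy"]] <- data.frame(
      query = pick,
      target = paste0("udecoy_", seq_along(pick)),
      tm_score = stats::runif(nd, 0.05, 0.45),
      query_coverage = stats::runif(nd, 0.85, 0.99),
      target_coverage = stats::runif(nd, 0.40, 0.99),
      stringsAsFactors = FALSE)
  }
  structure_hits <- if (length(sh)) do.call(rbind, sh) else
    empty_structure_hits()
  rownames(structure_hits) <- NULL

  fold_map <- data.frame(
    target_id = unique(structure_hits$target),
    stringsAsFactors = FALSE)
  fold_map$fold_id <- ifelse(
    grepl("^d_", fold_map$target_id),
    sub("^d_([a-z]\\.[0-9]+)_.*$", "\\1", fold_map$target_id),
    decoy_fold)

  # homology hits: planted escapees get only a decoy above the cutoff
  n_escaped <- round(spec$escape_fraction_among_assigned * n_assigned)
  escaped_ids <- assigned_ids[seq_len(n_escaped)]
  hit_ids <- c(setdiff(assigned_ids, escaped_ids), unassigned_ids)
  hh <- list()
  if (length(hit_ids)) {
    hh[["real"]] <- m8_rows(hit_ids, evalue = 1e-5)
  }
  if (length(escaped_ids)) {
    hh[["decoy"]] <- m8_rows(escaped_ids, evalue = 0.5)
  }
  homology_hits <- if (length(hh)) do.call(rbind, hh) else
    data.frame(query = character(0), target = character(0),
               evalue = numeric(0), stringsAsFactors = FALSE)
  rownames(homology_hits) <- NULL

  truth <- list(
    n_sequences = n,
    n_invalid = n_invalid,
    n_valid = n_valid,
    valid_fraction = n_valid / n,
    n_assigned = n_assigned,
    assigned_fraction = if (n_valid > 0) n_assigned / n_valid else 0,
    n_distinct_folds = if (n_assigned > 0) k else 0L,
    fold_counts = stats::setNames(as.list(fold_counts), folds),
    n_escaped = n_escaped,
    escape_fraction_among_assigned =
      if (n_assigned > 0) n_escaped / n_assigned else 0,
    reference_fold_total = spec$reference_fold_total,
    seed = spec$seed
  )

  out <- list(records = records, structure_hits = structure_hits,
              homology_hits = homology_hits, fold_map = fold_map,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(records, file.path(outdir, "sequences.fasta"))
    write_tsv_hash(structure_hits, file.path(outdir, "structure_hits.tsv"))
    write_m8(homology_hits, file.path(outdir, "homology_hits.m8"))
    write_tsv_hash(fold_map, file.path(outdir, "fold_map.tsv"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# Minimal full-width m8 rows (12 columns) for a set of queries.
m8_rows <- function(query_ids, evalue) {
  n <- length(query_ids)
  data.frame(query = query_ids,
             target = paste0("U50_", seq_len(n)),
             pident = 35.0, alnlen = 80L, mismatch = 40L, gapopen = 2L,
             qstart = 1L, qend = 80L, tstart = 1L, tend = 80L,
             evalue = evalue, bits = 60.0,
             stringsAsFactors = FALSE)
}

#' Toy coordinate sets in PDB format
#'
#' Minimal CA-only poly-glycine fixtures for the SASA code:
#' \describe{
#'   \item{isolated_residue}{one atom at the origin.}
#'   \item{ideal_helix}{CA trace with standard alpha-helix geometry (2.3
#'     Angstrom radius, 1.5 Angstrom rise, 100 degrees per residue).}
#'   \item{extended_chain}{residues spaced 120 Angstrom apart, far beyond
#'     probe contact, so SASA is exactly additive.}
#'   \item{compact_cluster}{the same residues packed inside a small sphere
#'     (pairwise contacts guaranteed), so burial exceeds the extended
#'     arrangement.}
#' }
#'
#' @param kind Fixture type.
#' @param n_residues Number of residues (default 1).
#' @param seed Seed for the compact cluster placement.
#' @return PDB-format text (one character scalar of ATOM records + END).
#' @export
make_toy_coordinates <- function(kind = c("isolated_residue", "ideal_helix",
                                          "extended_chain",
                                          "compact_cluster"),
                                 n_residues = 1L, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n_residues)
  stopifnot(n >= 1L)
  xyz <- switch(kind,
    isolated_residue = matrix(0, nrow = 1, ncol = 3),
    ideal_helix = {
      i <- seq_len(n) - 1L
      ang <- i * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    },
    extended_chain = cbind(120 * (seq_len(n) - 1L), 0, 0),
    compact_cluster = {
      set.seed(substream_seed(seed, 13L))
      r_cluster <- 2.0 * n^(1 / 3)
      pts <- matrix(NA_real_, nrow = n, ncol = 3)
      placed <- 0L
      while (placed < n) {
        cand <- stats::runif(3, -r_cluster, r_cluster)
        if (sum(cand^2) > r_cluster^2) next
        if (placed > 0L) {
          d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2)
          if (min(d2) < 1.5^2) next
        }
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
      pts
    })
  if (kind == "isolated_residue" && n > 1L) {
    stop("isolated_residue is a single-residue fixture")
  }
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), seq_len(nrow(xyz)),
    xyz[, 1], xyz[, 2], xyz[, 3])
  paste(c(lines, "END"), collapse = "\n")
}
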