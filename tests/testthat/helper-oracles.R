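# Shared fixtures and independent oracles used across test files.

# Total-variation distance between two named discrete distributions
# (match()-based so the empty-string key is handled).
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  a <- as.numeric(p)[match(keys, names(p))]
  b <- as.numeric(q)[match(keys, names(q))]
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  0.5 * sum(abs(a - b))
}

# Empirical distribution of a character vector of sequences.
empirical_distribution <- function(seqs) {
  tab <- table(seqs)
  stats::setNames(as.numeric(tab) / length(seqs), names(tab))
}

# Brute-force consensus-vote oracle: enumerate every candidate fold among
# the surviving hits, count votes, and apply the tie rule literally.
# Independent of the package's vote path.
oracle_consensus <- function(hits, fold_map, tm_min = 0.5, cov_min = 0.8) {
  surv <- hits[hits$tm_score > tm_min &
                 pmax(hits$query_coverage, hits$target_coverage) > cov_min, ,
               drop = FALSE]
  if (nrow(surv) == 0L) return(NA_character_)
  folds <- unname(fold_map[surv$target])
  candidates <- sort(unique(folds))
  nvotes <- vapply(candidates, function(f) sum(folds == f), integer(1))
  best <- candidates[nvotes == max(nvotes)]
  if (length(best) == 1L) return(best)
  tm_best <- vapply(best, function(f) max(surv$tm_score[folds == f]),
                    numeric(1))
  best <- best[tm_best == max(tm_best)]
  sort(best)[1L]
}

# Random single-query hit table over a small fold pool; coarse scores make
# plurality and tm ties frequent.
random_hit_table <- function(seed) {
  set.seed(seed)
  pool_folds <- c("a.1", "a.2", "b.1", "c.7")
  targets <- paste0("t", seq_len(8))
  fold_map <- stats::setNames(sample(pool_folds, 8, replace = TRUE), targets)
  n <- sample(0:8, 1)
  hits <- data.frame(
    query = rep("q1", n),
    target = sample(targets, n, replace = TRUE),
    tm_score = sample(seq(0.1, 0.9, by = 0.2), n, replace = TRUE),
    query_coverage = sample(c(0.5, 0.85, 0.95), n, replace = TRUE),
    target_coverage = sample(c(0.5, 0.85, 0.95), n, replace = TRUE),
    stringsAsFactors = FALSE)
  list(hits = hits, fold_map = fold_map)
}

# Deterministic distinct valid sequences: index encoded in base-20 letters.
index_sequences <- function(n, width = 6L) {
  alph <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  out <- character(n)
  idx <- seq_len(n) - 1L
  m <- matrix("A", nrow = n, ncol = width)
  for (j in seq_len(width)) {
    m[, j] <- alph[idx %% 20L + 1L]
    idx <- idx %/% 20L
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Records data.frame from bare sequences (zero-length safe).
records_from <- function(seqs, prefix = "s") {
  n <- length(seqs)
  data.frame(id = sprintf("%s%06d", prefix, seq_len(n)),
             description = rep("", n), sequence = seqs,
             source = rep("test", n), stringsAsFactors = FALSE)
}

# Parse PDB text (as returned by make_toy_coordinates) via a tempfile.
read_pdb_atoms_text <- function(text) {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(text, f)
  read_pdb_atoms(f)
}

# A masked-mode model emitting a fixed token everywhere, with STOP forced
# at a given position (0 = never).
fixed_masked_model <- function(stop_at = 0L) {
  vocab <- vocabulary(c("A", "C", "<stop>"), stop_index = 3L)
  token_model(vocab,
              next_fn = function(context) c(1, 0, 0),
              masked_fn = function(filled, position, length) {
                if (stop_at > 0L && position == stop_at) c(0, 0, 1)
                else c(1, 0, 0)
              },
              name = "fixed_masked")
}
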