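# Consensus fold assignment and fold-distribution statistics.

make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query = r[[1]], target = r[[2]], tm_score = as.numeric(r[[3]]),
               query_coverage = as.numeric(r[[4]]),
               target_coverage = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("structure hit parser validates ranges and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#query\ttarget\ttm\tqcov\ttcov",
               "q1\tt1\t0.6\t0.9\t0.5",
               "q1\tt2\t1.2\t0.9\t0.5",     # tm out of range
               "q2\tt3\tnot_a_number\t0.9\t0.5",
               "q2\tt4\t0.7\t0.85\t0.91"), path)
  expect_warning(hits <- parse_structure_hits(path), "rejected 2")
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$query, c("q1", "q2"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#header only", empty)
  expect_warning(h0 <- parse_structure_hits(empty), "no hit rows")
  expect_identical(nrow(h0), 0L)
})

test_that("consensus assignment counts votes with strict thresholds", {
  fm <- c(t1 = "a.1", t2 = "a.1", t3 = "b.1")
  hits <- make_hits(list("q", "t1", 0.6, 0.9, 0.1),
                    list("q", "t2", 0.55, 0.1, 0.85),
                    list("q", "t3", 0.7, 0.9, 0.1))
  a <- assign_consensus_fold(hits, fm)
  expect_identical(a$assigned_fold, "a.1")
  expect_identical(unname(a$vote_counts["a.1"]), 2L)
  expect_false(a$tie_broken)

  # below tm threshold (strict): no assignment
  low <- make_hits(list("q", "t1", 0.4, 0.99, 0.99))
  expect_true(is.na(assign_consensus_fold(low, fm)$assigned_fold))
  # exactly at the thresholds: strict > excludes
  at <- make_hits(list("q", "t1", 0.5, 0.8, 0.8))
  expect_true(is.na(assign_consensus_fold(at, fm)$assigned_fold))
})

test_that("plurality ties break by max tm then lexicographic fold id", {
  fm <- c(t1 = "a.1", t2 = "b.1", t3 = "a.2")
  tie_tm <- make_hits(list("q", "t1", 0.6, 0.9, 0.1),
                      list("q", "t2", 0.8, 0.9, 0.1))
  a <- assign_consensus_fold(tie_tm, fm)
  expect_identical(a$assigned_fold, "b.1")
  expect_true(a$tie_broken)

  # identical tm as well: lexicographic fold id wins
  tie_lex <- make_hits(list("q", "t2", 0.7, 0.9, 0.1),
                       list("q", "t3", 0.7, 0.9, 0.1))
  b <- assign_consensus_fold(tie_lex, fm)
  expect_identical(b$assigned_fold, "a.2")
  expect_true(b$tie_broken)
})

test_that("consensus assignment equals the brute-force vote oracle", {
  for (seed in 1:400) {
    tbl <- random_hit_table(seed)
    got <- assign_consensus_fold(tbl$hits, tbl$fold_map)$assigned_fold
    want <- oracle_consensus(tbl$hits, tbl$fold_map)
    expect_identical(got, want)
  }
})

test_that("assignment errors on unknown targets and mixed queries", {
  fm <- c(t1 = "a.1")
  orphan <- make_hits(list("q", "tX", 0.9, 0.9, 0.9))
  expect_error(assign_consensus_fold(orphan, fm), "tX")
  mixed <- make_hits(list("q1", "t1", 0.9, 0.9, 0.9),
                     list("q2", "t1", 0.9, 0.9, 0.9))
  expect_error(assign_consensus_fold(mixed, fm), "multiple queries")
  expect_error(assign_consensus_fold(orphan, c(t1 = "bad_fold")), "fold ids")
})

test_that("batch annotation covers the query universe; hit rate follows", {
  fm <- c(t1 = "a.1", t2 = "b.1")
  hits <- make_hits(list("q1", "t1", 0.9, 0.9, 0.9),
                    list("q2", "t2", 0.3, 0.9, 0.9))   # fails tm
  ann <- annotate_folds(hits, fm, query_ids = c("q1", "q2", "q3"))
  expect_identical(nrow(ann), 3L)
  expect_identical(ann$fold, c("a.1", NA, NA))
  expect_identical(ann$class, c("a", NA, NA))
  expect_equal(structural_hit_rate(ann), 1 / 3)
  expect_warning(r0 <- structural_hit_rate(ann[0, ]), "no annotations")
  expect_equal(r0, 0)
})

test_that("raising thresholds never increases assigned queries", {
  set.seed(42)
  n <- 300
  hits <- data.frame(query = paste0("q", sample(1:60, n, replace = TRUE)),
                     target = "t1",
                     tm_score = runif(n), query_coverage = runif(n),
                     target_coverage = runif(n), stringsAsFactors = FALSE)
  fm <- c(t1 = "a.1")
  n_assigned <- function(tm_min, cov_min) {
    ann <- annotate_folds(hits, fm, annotation_config(tm_min, cov_min),
                          query_ids = paste0("q", 1:60))
    sum(!is.na(ann$fold))
  }
  for (th in list(c(0.3, 0.5), c(0.5, 0.5), c(0.5, 0.8), c(0.7, 0.8))) {
    expect_gte(n_assigned(th[1], th[2]), n_assigned(min(th[1] + 0.2, 0.95), th[2]))
    expect_gte(n_assigned(th[1], th[2]), n_assigned(th[1], min(th[2] + 0.15, 0.95)))
  }
})

test_that("fold inventory and coverage recover planted fractions", {
  ann <- data.frame(query_id = paste0("q", 1:10),
                    fold = c(rep("a.1", 4), rep("c.3", 3), "b.2", NA, NA),
                    stringsAsFactors = FALSE)
  ann$class <- sub("\\..*$", "", ann$fold)
  inv <- fold_inventory(ann, reference_total = 20)
  expect_identical(inv$n_folds, 3L)
  expect_identical(unname(inv$counts["a.1"]), 4L)
  expect_equal(inv$coverage, 3 / 20)
  inv0 <- fold_inventory(ann[is.na(ann$fold), ])
  expect_identical(inv0$n_folds, 0L)
  expect_equal(inv0$coverage, 0)
})

test_that("topology distribution sums to one over assigned classes", {
  ann <- data.frame(query_id = paste0("q", 1:8),
                    fold = c("a.1", "a.2", "c.1", "c.9", NA, "a.3", "c.2", NA),
                    stringsAsFactors = FALSE)
  ann$class <- sub("\\..*$", "", ann$fold)
  td <- topology_distribution(ann)
  expect_equal(sum(td), 1, tolerance = 1e-9)
  expect_equal(unname(td["a"]), 0.5)
  expect_equal(unname(td["c"]), 0.5)
})

test_that("fold enrichment is zero on identity, ~+3 at 8x, antisymmetric", {
  g <- c(a.1 = 100L, b.1 = 100L, c.1 = 100L)
  expect_true(all(abs(fold_enrichment(g, g)) < 1e-12))

  # one fold 8x overrepresented at matched totals
  g2 <- c(a.1 = 800L, b.1 = 100L, c.1 = 100L)
  n2 <- c(a.1 = 100L, b.1 = 450L, c.1 = 450L)
  e <- fold_enrichment(g2, n2)
  expect_lt(abs(e["a.1"] - 3), 0.05)
  expect_equal(unname(fold_enrichment(n2, g2)), unname(-e), tolerance = 1e-12)
  expect_error(fold_enrichment(stats::setNames(integer(0), character(0)),
                               stats::setNames(integer(0), character(0))),
               "empty fold universe")
})

test_that("reciprocal filtering demands both directions and both coverages", {
  ab <- make_hits(list("A1", "B1", 0.7, 0.9, 0.85),
                  list("A2", "B2", 0.7, 0.9, 0.85),   # missing in B->A
                  list("A3", "B3", 0.7, 0.9, 0.70))   # tcov fails "both"
  ba <- make_hits(list("B1", "A1", 0.65, 0.88, 0.9),
                  list("B3", "A3", 0.7, 0.9, 0.9),
                  list("B1", "A1", 0.65, 0.88, 0.9))  # exact duplicate
  pairs <- reciprocal_filter(ab, ba)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$id_a, "A1")
  expect_identical(pairs$id_b, "B1")
})
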