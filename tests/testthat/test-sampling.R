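# Decoding transforms and generation engines.

test_that("temperature transform matches closed-form softmax and limits", {
  expect_equal(apply_temperature(c(3, 3), 1), c(0.5, 0.5))
  expect_equal(apply_temperature(c(-1, -1), 7), c(0.5, 0.5))
  expect_equal(apply_temperature(c(log(2), 0), 1), c(2 / 3, 1 / 3))
  # T -> Inf flattens toward uniform
  hot <- apply_temperature(c(5, 0, -5), 1e5)
  expect_true(all(abs(hot - 1 / 3) < 1e-4))
  # T -> 0 concentrates on the argmax of a gapped distribution
  cold <- apply_temperature(log(c(0.6, 0.3, 0.1)), 1e-3)
  expect_gt(cold[1], 0.999)
  expect_error(apply_temperature(c(0, 1), 0), "temperature")
  expect_error(apply_temperature(c(0, 1), -2), "temperature")
})

test_that("temperature preserves token ranking", {
  set.seed(11)
  for (i in 1:20) {
    logits <- rnorm(6)
    for (temp in c(0.2, 0.7, 1, 1.8, 5)) {
      expect_identical(order(apply_temperature(logits, temp)), order(logits))
    }
  }
})

test_that("top-k filter keeps the k most probable tokens, renormalized", {
  expect_equal(filter_top_k(c(0.5, 0.3, 0.2), 1), c(1, 0, 0))
  expect_equal(filter_top_k(c(0.5, 0.3, 0.2), 3), c(0.5, 0.3, 0.2))
  expect_equal(filter_top_k(c(0.5, 0.3, 0.2), 2), c(0.625, 0.375, 0))
  expect_error(filter_top_k(c(0.5, 0.5), 0), "k must lie")
  expect_error(filter_top_k(c(0.5, 0.5), 3), "k must lie")
})

test_that("nucleus filter keeps the smallest prefix reaching mass p", {
  expect_equal(filter_top_p(c(0.5, 0.3, 0.2), 1), c(0.5, 0.3, 0.2))
  expect_equal(filter_top_p(c(0.5, 0.3, 0.2), 0.6), c(0.625, 0.375, 0))
  expect_equal(filter_top_p(c(1, 0, 0), 0.01), c(1, 0, 0))
  expect_error(filter_top_p(c(1, 0), 0), "p must lie")
  expect_error(filter_top_p(c(1, 0), 1.5), "p must lie")
})

test_that("repetition penalty is sign-dependent and identity at 1", {
  logits <- c(1.2, -1.0, 0.4)
  expect_identical(apply_repetition_penalty(logits, integer(0), 1.2), logits)
  expect_identical(apply_repetition_penalty(logits, 1:3, 1), logits)
  out <- apply_repetition_penalty(logits, c(1, 2), 1.2)
  expect_equal(out, c(1.0, -1.2, 0.4))
  expect_error(apply_repetition_penalty(logits, 1, 0.9), "penalty")
})

test_that("transform chain at neutral parameters is the identity", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(7)
    p[sample(7, 2)] <- 0
    p <- p / sum(p)
    neutral <- sampling_params(temperature = 1, top_k = 7, top_p = 1,
                               repetition_penalty = 1)
    out <- foldcensus:::step_distribution(p, neutral, history = c(1L, 3L))
    expect_equal(out, p, tolerance = 1e-9)
  }
})

test_that("per-step support never shrinks as top_k or temperature grows", {
  p <- c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)
  support <- function(params) {
    sum(foldcensus:::step_distribution(p, params) > 0)
  }
  ks <- 1:6
  s_k <- vapply(ks, function(k) support(sampling_params(top_k = k,
                                                        repetition_penalty = 1)),
                numeric(1))
  expect_true(all(diff(s_k) >= 0))
  temps <- c(0.3, 0.8, 1, 1.5, 3)
  s_t <- vapply(temps, function(temp)
    support(sampling_params(temperature = temp, top_k = 6,
                            repetition_penalty = 1)), numeric(1))
  expect_true(all(diff(s_t) >= 0))
})

test_that("sample_next_token reproduces a uniform model's frequencies", {
  vocab <- vocabulary(c("A", "C", "D", "E"), stop_index = 4L)
  model <- token_model(vocab, function(context) rep(0.25, 4))
  params <- sampling_params(top_k = 4, repetition_penalty = 1)
  set.seed(101)
  draws <- replicate(20000, sample_next_token(model, integer(0), params))
  freqs <- tabulate(draws, 4) / 20000
  expect_true(all(abs(freqs - 0.25) < 0.01))
})

test_that("autoregressive generation terminates, truncates and echoes params", {
  # degenerate: STOP always first -> empty sequences
  vocab <- vocabulary(c("A", "<stop>"), stop_index = 2L)
  stop_model <- token_model(vocab, function(context) c(0, 1))
  recs <- generate_autoregressive(stop_model,
                                  sampling_params(top_k = 2,
                                                  repetition_penalty = 1),
                                  n = 5, seed = 1)
  expect_identical(recs$sequence, rep("", 5))
  expect_false(any(valid_mask <- vapply(recs$sequence, function(s)
    is_valid_sequence(s)$valid, logical(1))))

  # fixed 3-residue subword token: 40 tokens = 120 residues, truncated to 100
  vocab3 <- vocabulary(c("GAS", "<stop>"), stop_index = 2L)
  triple <- token_model(vocab3, function(context) c(1, 0))
  recs3 <- generate_autoregressive(triple,
                                   sampling_params(top_k = 2,
                                                   repetition_penalty = 1),
                                   n = 2, seed = 1)
  expect_identical(nchar(recs3$sequence), c(100L, 100L))
  expect_identical(substr(recs3$sequence[1], 1, 6), "GASGAS")
  expect_s3_class(attr(recs3, "params"), "fc_sampling_params")
})

test_that("fixed seed gives bit-identical batches; seeds differ otherwise", {
  model <- make_toy_markov_model(4, "random", seed = 2)
  params <- sampling_params(top_k = 4, max_tokens = 6, seed = 3)
  a <- generate_autoregressive(model, params, n = 50, seed = 3)
  b <- generate_autoregressive(model, params, n = 50, seed = 3)
  expect_identical(a, b)
  c <- generate_autoregressive(model, params, n = 50, seed = 4)
  expect_false(identical(a$sequence, c$sequence))
  g1 <- generate_gibbs_lr(model, gibbs_params(max_residues = 20), n = 20,
                          seed = 5)
  g2 <- generate_gibbs_lr(model, gibbs_params(max_residues = 20), n = 20,
                          seed = 5)
  expect_identical(g1, g2)
})

test_that("empirical autoregressive output matches exhaustive enumeration", {
  model <- make_toy_markov_model(3, "two_mode")
  params <- sampling_params(top_k = 3, repetition_penalty = 1.2,
                            max_tokens = 4)
  truth <- enumerate_sequence_distribution(model, params, max_len = 4)
  expect_equal(sum(truth), 1, tolerance = 1e-9)
  recs <- generate_autoregressive(model, params, n = 20000, seed = 17)
  expect_lt(tv_distance(truth, empirical_distribution(recs$sequence)), 0.02)
})

test_that("enumeration handles deterministic and uniform chains exactly", {
  chain <- make_toy_markov_model(4, "chain")
  d <- enumerate_sequence_distribution(chain,
                                       sampling_params(top_k = 4,
                                                       repetition_penalty = 1,
                                                       max_tokens = 6),
                                       max_len = 6)
  expect_identical(names(d), "ACD")
  expect_equal(unname(d), 1)

  # 2 residue tokens + never-stopping uniform model: 8 equiprobable 3-mers
  vocab <- vocabulary(c("A", "C", "<stop>"), stop_index = 3L)
  nostop <- token_model(vocab, function(context) c(0.5, 0.5, 0))
  d8 <- enumerate_sequence_distribution(nostop,
                                        sampling_params(top_k = 3,
                                                        repetition_penalty = 1),
                                        max_len = 3)
  expect_length(d8, 8)
  expect_true(all(abs(d8 - 1 / 8) < 1e-12))
  expect_error(
    enumerate_sequence_distribution(nostop, sampling_params(), max_len = 30),
    "path budget")
})

test_that("Gibbs left-to-right pass fills the template and honours STOP", {
  all_a <- fixed_masked_model(stop_at = 0L)
  recs <- generate_gibbs_lr(all_a, gibbs_params(max_residues = 100), n = 3,
                            seed = 1)
  expect_identical(recs$sequence, rep(strrep("A", 100), 3))

  stops51 <- fixed_masked_model(stop_at = 51L)
  recs51 <- generate_gibbs_lr(stops51, gibbs_params(max_residues = 100),
                              n = 3, seed = 1)
  expect_identical(nchar(recs51$sequence), rep(50L, 3))

  # position-independent marginals are recovered per position
  vocab <- vocabulary(c("A", "C", "<stop>"), stop_index = 3L)
  marg <- c(0.7, 0.3, 0)
  mm <- token_model(vocab, function(context) marg,
                    masked_fn = function(filled, position, length) marg)
  recs_m <- generate_gibbs_lr(mm, gibbs_params(max_residues = 30), n = 4000,
                              seed = 8)
  first_pos <- substr(recs_m$sequence, 1, 1)
  expect_lt(abs(mean(first_pos == "A") - 0.7), 0.02)

  ar_only <- token_model(vocab, function(context) marg)
  expect_error(generate_gibbs_lr(ar_only, gibbs_params(), n = 1),
               "masked mode")
})

test_that("background sampler is exact-length, alphabet-closed and unbiased", {
  one_hot <- stats::setNames(rep(0, 20), names(natural_abundances()))
  one_hot["G"] <- 1
  bg <- background_model(one_hot, length = 5)
  recs <- generate_background(bg, 4, seed = 1)
  expect_identical(recs$sequence, rep("GGGGG", 4))

  unif <- stats::setNames(rep(0.05, 20), names(natural_abundances()))
  recs_u <- generate_background(background_model(unif, length = 100), 2000,
                                seed = 2)
  expect_true(all(nchar(recs_u$sequence) == 100))
  expect_false(any(grepl("[BJOUXZ]", recs_u$sequence)))
  chars <- strsplit(paste(recs_u$sequence, collapse = ""), "")[[1]]
  freqs <- table(chars) / length(chars)
  expect_true(all(abs(freqs - 0.05) < 0.005))
})
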