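# Decoding transforms and generation engines.

#' Decoding hyperparameters
#'
#' All knobs of the sampling transform chain plus termination limits. The
#' per-step transform order is: repetition penalty (on log-probabilities),
#' temperature, top-k, top-p (nucleus), renormalize.
#'
#' Defaults correspond to standard autoregressive decoding settings for
#' subword protein language models: temperature 1, top-k 950, top-p 1,
#' repetition penalty 1.2, at most 40 tokens per sequence and truncation of
#' the residue string at 100 amino acids. For left-to-right Gibbs decoding of
#' masked models use [gibbs_params()] (temperature 1, no penalty, full token
#' distribution, 100 positions).
#'
#' @param temperature Positive real; divides log-probabilities before
#'   renormalization. Values above 1 flatten the distribution, values below 1
#'   sharpen it.
#' @param top_k Integer pool size: only the `top_k` most probable tokens
#'   remain sampleable. `NULL` (or any value at least the vocabulary size)
#'   keeps the full distribution.
#' @param top_p Nucleus mass in (0, 1]: the smallest set of top tokens whose
#'   cumulative probability reaches `top_p` remains sampleable. 1 keeps all.
#' @param repetition_penalty Real >= 1; CTRL-style sign-dependent logit
#'   penalty applied to tokens already emitted in the current sequence.
#' @param max_tokens Autoregressive step cap (STOP counts as a step).
#' @param max_residues Residue-length cap; longer concatenations are
#'   truncated.
#' @param seed Default random seed for the engines.
#' @return An object of class `fc_sampling_params`.
#' @export
sampling_params <- function(temperature = 1, top_k = 950L, top_p = 1,
                            repetition_penalty = 1.2, max_tokens = 40L,
                            max_residues = 100L, seed = 1L) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("temperature must be a positive real")
  }
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (is.na(top_k) || top_k < 1L) stop("top_k must be a positive integer")
  }
  if (!is.numeric(top_p) || length(top_p) != 1L || is.na(top_p) ||
      top_p <= 0 || top_p > 1) {
    stop("top_p must lie in (0, 1]")
  }
  if (!is.numeric(repetition_penalty) || is.na(repetition_penalty) ||
      repetition_penalty < 1) {
    stop("repetition_penalty must be >= 1")
  }
  max_tokens <- as.integer(max_tokens)
  max_residues <- as.integer(max_residues)
  if (is.na(max_tokens) || max_tokens < 1L) stop("max_tokens must be >= 1")
  if (is.na(max_residues) || max_residues < 1L) stop("max_residues must be >= 1")
  structure(list(temperature = temperature, top_k = top_k, top_p = top_p,
                 repetition_penalty = repetition_penalty,
                 max_tokens = max_tokens, max_residues = max_residues,
                 seed = as.integer(seed)),
            class = "fc_sampling_params")
}

#' @rdname sampling_params
#' @param ... Overrides passed on to [sampling_params()].
#' @export
gibbs_params <- function(...) {
  defaults <- list(temperature = 1, top_k = NULL, top_p = 1,
                   repetition_penalty = 1, max_tokens = 100L,
                   max_residues = 100L, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sampling_params, args)
}

#' @export
print.fc_sampling_params <- function(x, ...) {
  cat("<sampling params> T=", x$temperature,
      " top_k=", if (is.null(x$top_k)) "all" else x$top_k,
      " top_p=", x$top_p, " rep_penalty=", x$repetition_penalty,
      " max_tokens=", x$max_tokens, " max_residues=", x$max_residues,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Temperature transform
#'
#' Softmax of `logits / temperature`. Temperatures above 1 flatten the
#' distribution over the token pool; below 1 they concentrate mass on the top
#' tokens. The ranking of tokens is preserved for any temperature.
#'
#' @param logits Numeric vector of (unnormalized) log scores; `-Inf` entries
#'   denote excluded tokens.
#' @param temperature Positive real.
#' @return Probability vector summing to 1.
#' @export
apply_temperature <- function(logits, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("temperature must be a positive real")
  }
  if (any(is.na(logits)) || any(logits == Inf)) {
    stop("logits must be finite (or -Inf for excluded tokens)")
  }
  z <- logits / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Top-k filter
#'
#' Zeroes all but the `k` highest-probability entries and renormalizes the
#' survivors. Ties at the pool boundary are broken by original position
#' (stable order).
#'
#' @param probs Probability vector.
#' @param k Integer in `[1, length(probs)]`.
#' @return Filtered, renormalized probability vector.
#' @export
filter_top_k <- function(probs, k) {
  check_probs_arg(probs)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(probs)) {
    stop("k must lie in [1, ", length(probs), "]")
  }
  if (k == length(probs)) return(probs)
  keep <- order(probs, decreasing = TRUE)[seq_len(k)]
  out <- numeric(length(probs))
  out[keep] <- probs[keep]
  out / sum(out)
}

#' Top-p (nucleus) filter
#'
#' Retains the smallest prefix of the descending-sorted probabilities whose
#' cumulative mass reaches `p`, and renormalizes. `p = 1` is the identity.
#'
#' @param probs Probability vector.
#' @param p Real in (0, 1].
#' @return Filtered, renormalized probability vector.
#' @export
filter_top_p <- function(probs, p) {
  check_probs_arg(probs)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("p must lie in (0, 1]")
  }
  if (p == 1) return(probs)
  ord <- order(probs, decreasing = TRUE)
  cs <- cumsum(probs[ord])
  ncut <- which(cs >= p - 1e-12)[1L]
  if (is.na(ncut)) ncut <- length(probs)
  keep <- ord[seq_len(ncut)]
  out <- numeric(length(probs))
  out[keep] <- probs[keep]
  out / sum(out)
}

#' Repetition penalty (CTRL-style)
#'
#' For every token index in `history`, positive logits are divided by
#' `penalty` and negative logits multiplied by it, discouraging re-emission.
#' Other logits are unchanged; `penalty = 1` is the identity.
#'
#' @param logits Numeric vector of log scores.
#' @param history Integer vector of token indices already emitted.
#' @param penalty Real >= 1.
#' @return Adjusted logit vector (not renormalized).
#' @export
apply_repetition_penalty <- function(logits, history, penalty) {
  if (!is.numeric(penalty) || is.na(penalty) || penalty < 1) {
    stop("penalty must be >= 1")
  }
  history <- unique(as.integer(history))
  if (length(history) == 0L || penalty == 1) return(logits)
  h <- logits[history]
  logits[history] <- ifelse(h > 0, h / penalty, h * penalty)
  logits
}

check_probs_arg <- function(probs) {
  if (!is.numeric(probs) || any(is.na(probs)) || any(probs < 0)) {
    stop("probs must be a non-negative numeric vector")
  }
  if (abs(sum(probs) - 1) > 1e-6) {
    stop("probs must sum to 1")
  }
  invisible(probs)
}

# Full per-step transform chain: penalty -> temperature -> top_k -> top_p ->
# renormalize. At neutral parameters (T=1, k>=|V|, p=1, penalty=1) this is
# the exact identity on the model distribution.
step_distribution <- function(probs, params, history = integer(0)) {
  p <- probs
  if (params$repetition_penalty > 1 && length(history)) {
    lg <- suppressWarnings(log(p))       # zeros -> -Inf, handled downstream
    lg <- apply_repetition_penalty(lg, history, params$repetition_penalty)
    p <- apply_temperature(lg, params$temperature)
  } else if (params$temperature != 1) {
    p <- apply_temperature(suppressWarnings(log(p)), params$temperature)
  }
  k <- params$top_k
  if (!is.null(k) && k < length(p)) p <- filter_top_k(p, k)
  if (params$top_p < 1) p <- filter_top_p(p, params$top_p)
  s <- sum(p)
  if (s <= 0) stop("internal error: zero mass after filtering")
  if (s != 1) p <- p / s
  p
}

#' Draw one token through the transform chain
#'
#' Applies, in order, repetition penalty, temperature, top-k, top-p, and
#' renormalization to the model's conditional distribution for `context`,
#' then draws one token index using the current RNG state.
#'
#' @param model A [token_model()].
#' @param context Integer vector of token indices (left context).
#' @param params A [sampling_params()] object.
#' @return A single token index.
#' @export
sample_next_token <- function(model, context, params = sampling_params()) {
  probs <- model_probs(model, context)
  d <- step_distribution(probs, params, history = unique(as.integer(context)))
  sample.int(length(d), 1L, prob = d)
}

# Independent per-sequence RNG substream seeds: index i maps to a distinct
# residue mod the Mersenne prime 2^31-1, so streams never collide for
# i < 2^31-1 and generation is order-independent / parallelizable.
substream_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((as.double(seed %% m) + as.double(i) * 48271) %% m)
}

new_sequence_records <- function(id, sequence, source, params = NULL) {
  out <- data.frame(id = id, description = "", sequence = sequence,
                    source = source, stringsAsFactors = FALSE)
  if (!is.null(params)) attr(out, "params") <- params
  out
}

#' Autoregressive (left-to-right) generation
#'
#' Builds each sequence token by token: at every step the model's next-token
#' distribution is passed through the transform chain and one token is drawn.
#' Generation stops at the STOP token or after `max_tokens` steps; the
#' concatenated residue string is then truncated to `max_residues`
#' (multi-residue tokens are kept whole before truncation). Each sequence
#' uses its own RNG substream derived from `seed`, so results are
#' reproducible and independent of batch splitting.
#'
#' @param model A [token_model()].
#' @param params A [sampling_params()] object.
#' @param n Number of sequences.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A `data.frame` of sequence records (`id`, `description`,
#'   `sequence`, `source`) with the parameters attached as attribute
#'   `"params"`. Sequences may be empty if STOP is drawn first.
#' @export
generate_autoregressive <- function(model, params = sampling_params(), n,
                                    seed = params$seed) {
  stopifnot(inherits(model, "fc_token_model"), n >= 1)
  n <- as.integer(n)
  vocab <- model$vocab
  stop_idx <- vocab$stop_index
  toks <- vocab$tokens
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    context <- integer(0)
    for (step in seq_len(params$max_tokens)) {
      probs <- model_probs(model, context)
      d <- step_distribution(probs, params, history = unique(context))
      idx <- sample.int(length(d), 1L, prob = d)
      if (idx == stop_idx) break
      context <- c(context, idx)
    }
    s <- paste(toks[context], collapse = "")
    if (nchar(s) > params$max_residues) {
      s <- substr(s, 1L, params$max_residues)
    }
    seqs[i] <- s
  }
  new_sequence_records(sprintf("ar_%06d", seq_len(n)), seqs,
                       paste0(model$name, ":autoregressive"), params)
}

#' Left-to-right Gibbs generation for masked models
#'
#' Fills a fixed-length masked template of `max_residues` positions one
#' position at a time, left to right, in a single pass: each draw is
#' conditioned on the filled left context while the remaining positions stay
#' masked. STOP is sampleable at any position and cuts the sequence before
#' it. Requires a model with masked mode and a single-residue token
#' vocabulary (one template position holds one residue).
#'
#' @inheritParams generate_autoregressive
#' @param params A [sampling_params()] object; see [gibbs_params()] for the
#'   conventional masked-decoding defaults.
#' @return A `data.frame` of sequence records.
#' @export
generate_gibbs_lr <- function(model, params = gibbs_params(), n,
                              seed = params$seed) {
  stopifnot(inherits(model, "fc_token_model"), n >= 1)
  if (is.null(model$masked_fn)) {
    stop("generate_gibbs_lr requires a model with masked mode")
  }
  vocab <- model$vocab
  if (any(nchar(vocab$tokens[-vocab$stop_index]) != 1L)) {
    stop("Gibbs decoding requires a single-residue token vocabulary")
  }
  n <- as.integer(n)
  stop_idx <- vocab$stop_index
  toks <- vocab$tokens
  L <- params$max_residues
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    filled <- integer(0)
    for (pos in seq_len(L)) {
      probs <- model_masked_probs(model, filled, pos, L)
      d <- step_distribution(probs, params, history = unique(filled))
      idx <- sample.int(length(d), 1L, prob = d)
      if (idx == stop_idx) break
      filled <- c(filled, idx)
    }
    seqs[i] <- paste(toks[filled], collapse = "")
  }
  new_sequence_records(sprintf("gibbs_%06d", seq_len(n)), seqs,
                       paste0(model$name, ":gibbs_lr"), params)
}

#' Background control generation
#'
#' Draws `n` sequences of exactly `background$length` residues, each position
#' i.i.d. from the abundance distribution. By construction the output
#' contains no STOP, no rare/ambiguous letters and needs no truncation or
#' filtering.
#'
#' @param background A [background_model()].
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @return A `data.frame` of sequence records.
#' @export
generate_background <- function(background, n, seed = 1L) {
  stopifnot(inherits(background, "fc_background_model"), n >= 1)
  n <- as.integer(n)
  set.seed(substream_seed(seed, 0L))
  L <- background$length
  letters20 <- names(background$abundances)
  draws <- sample(letters20, n * L, replace = TRUE,
                  prob = background$abundances)
  m <- matrix(draws, nrow = n, ncol = L)
  seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  new_sequence_records(sprintf("bg_%06d", seq_len(n)), seqs, "background")
}

#' Exact output distribution by path enumeration
#'
#' Exhaustively enumerates every token path of up to `max_len` steps under
#' the same per-step transform chain as [sample_next_token()], accumulating
#' the exact probability of each terminated-or-truncated residue string.
#' Serves as the independent oracle for the sampling engines on toy models.
#'
#' @param model A [token_model()].
#' @param params A [sampling_params()] object.
#' @param max_len Token-step cap (analogous to `max_tokens`); the path budget
#'   `|V|^max_len` must not exceed 1e6.
#' @return Named numeric vector mapping each reachable output sequence
#'   (possibly `""`) to its exact probability; sums to 1.
#' @export
enumerate_sequence_distribution <- function(model, params = sampling_params(),
                                            max_len) {
  stopifnot(inherits(model, "fc_token_model"))
  max_len <- as.integer(max_len)
  nv <- model$vocab$n
  if (nv^max_len > 1e6) {
    stop("path budget exceeded: |V|^max_len = ", nv^max_len, " > 1e6")
  }
  stop_idx <- model$vocab$stop_index
  toks <- model$vocab$tokens
  acc <- new.env(parent = emptyenv())
  emit <- function(context, prob) {
    s <- paste(toks[context], collapse = "")
    if (nchar(s) > params$max_residues) s <- substr(s, 1L, params$max_residues)
    key <- paste0(".", s)        # sentinel prefix: "" is not a legal env name
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
  }
  recurse <- function(context, prob) {
    probs <- model_probs(model, context)
    d <- step_distribution(probs, params, history = unique(context))
    for (idx in which(d > 0)) {
      p2 <- prob * d[idx]
      if (idx == stop_idx) {
        emit(context, p2)
      } else if (length(context) + 1L >= max_len) {
        emit(c(context, idx), p2)
      } else {
        recurse(c(context, idx), p2)
      }
    }
  }
  recurse(integer(0), 1)
  keys <- ls(acc, all.names = TRUE)
  out <- vapply(keys, function(k) acc[[k]], numeric(1), USE.NAMES = FALSE)
  names(out) <- substring(keys, 2L)
  sort(out, decreasing = TRUE)
}
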