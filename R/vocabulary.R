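# Vocabularies and pluggable token-probability models.

# The 20 proteinogenic amino acids, one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Rare / ambiguous one-letter codes excluded from generated sequences.
FORBIDDEN_LETTERS <- c("B", "J", "O", "U", "X", "Z")

#' Construct a decoding vocabulary
#'
#' A vocabulary is an ordered set of tokens over the 20-letter amino-acid
#' alphabet -- single residues or multi-residue "subword" tokens -- plus one
#' distinguished STOP token that terminates generation and contributes no
#' residues.
#'
#' @param tokens Character vector of unique, non-empty tokens. Every token
#'   except the STOP token must consist only of the 20 standard one-letter
#'   amino-acid codes.
#' @param stop_index Integer index (1-based) of the STOP token within `tokens`.
#' @return An object of class `fc_vocabulary` with elements `tokens`,
#'   `stop_index` and `n`.
#' @examples
#' vocabulary(c("A", "C", "<stop>"), stop_index = 3)
#' @export
vocabulary <- function(tokens, stop_index) {
  tokens <- as.character(tokens)
  if (length(tokens) < 2L) stop("a vocabulary needs at least 2 tokens")
  if (anyDuplicated(tokens)) stop("vocabulary tokens must be unique")
  if (any(!nzchar(tokens))) stop("vocabulary tokens must be non-empty")
  stop_index <- as.integer(stop_index)
  if (length(stop_index) != 1L || is.na(stop_index) ||
      stop_index < 1L || stop_index > length(tokens)) {
    stop("stop_index must index a token in the vocabulary")
  }
  residue_tokens <- tokens[-stop_index]
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
               residue_tokens)
  if (any(bad)) {
    stop("non-STOP tokens must be over the 20-letter amino-acid alphabet; ",
         "offending: ", paste(residue_tokens[bad], collapse = ", "))
  }
  structure(list(tokens = tokens, stop_index = stop_index,
                 n = length(tokens)),
            class = "fc_vocabulary")
}

#' @export
print.fc_vocabulary <- function(x, ...) {
  cat("<vocabulary> ", x$n, " tokens, STOP = '",
      x$tokens[x$stop_index], "' (index ", x$stop_index, ")\n", sep = "")
  invisible(x)
}

#' Construct a token-probability model
#'
#' A token model is the seam between the decoding engines and any real or toy
#' generative model. It supplies conditional next-token distributions
#' (autoregressive mode) and, optionally, distributions for one masked
#' position in a fixed-length template (masked mode, used by the left-to-right
#' Gibbs engine).
#'
#' Both callbacks must be deterministic in their arguments and return a
#' non-negative vector over the vocabulary summing to 1 (within 1e-9).
#'
#' @param vocab An [vocabulary()] object.
#' @param next_fn Function `(context)` taking an integer vector of token
#'   indices (the left context, possibly empty) and returning a probability
#'   vector of length `vocab$n`.
#' @param masked_fn Optional function `(filled, position, length)` returning
#'   the conditional distribution for `position` in a template of `length`
#'   positions, given `filled` (indices at positions `1:(position-1)`); the
#'   remaining positions are masked. `NULL` if the model is autoregressive
#'   only.
#' @param name Model tag recorded in generated records' `source` field.
#' @return An object of class `fc_token_model`.
#' @export
token_model <- function(vocab, next_fn, masked_fn = NULL, name = "token_model") {
  stopifnot(inherits(vocab, "fc_vocabulary"), is.function(next_fn))
  if (!is.null(masked_fn)) stopifnot(is.function(masked_fn))
  structure(list(vocab = vocab, next_fn = next_fn, masked_fn = masked_fn,
                 name = name),
            class = "fc_token_model")
}

#' @export
print.fc_token_model <- function(x, ...) {
  cat("<token model> '", x$name, "', |V| = ", x$vocab$n,
      if (is.null(x$masked_fn)) ", autoregressive" else
        ", autoregressive + masked", "\n", sep = "")
  invisible(x)
}

# Fetch and validate a model's conditional distribution.
model_probs <- function(model, context) {
  p <- model$next_fn(as.integer(context))
  check_prob_vector(p, model$vocab$n)
  p
}

model_masked_probs <- function(model, filled, position, length) {
  if (is.null(model$masked_fn)) {
    stop("token model '", model$name, "' does not support masked mode")
  }
  p <- model$masked_fn(as.integer(filled), position, length)
  check_prob_vector(p, model$vocab$n)
  p
}

check_prob_vector <- function(p, n) {
  if (length(p) != n) {
    stop("model returned a vector of length ", length(p),
         ", expected |V| = ", n)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("model distribution must be non-negative and sum to 1 within 1e-9")
  }
  invisible(p)
}

#' Background (natural-abundance) sequence model
#'
#' Position-independent control model: each residue is drawn i.i.d. from a
#' fixed abundance distribution over the 20 standard amino acids. Emulates a
#' random-sequence control preserving first-order composition statistics but
#' none of the higher-order correlations a language model captures.
#'
#' @param abundances Named non-negative vector over the 20 standard amino
#'   acids, summing to 1 within 1e-9. Default: SwissProt-like natural
#'   abundances.
#' @param length Sequence length in residues (default 100).
#' @return An object of class `fc_background_model`.
#' @export
background_model <- function(abundances = natural_abundances(), length = 100L) {
  if (is.null(names(abundances)) ||
      !setequal(names(abundances), AA_ALPHABET)) {
    stop("abundances must be named by the 20 standard amino acids")
  }
  abundances <- abundances[AA_ALPHABET]
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must be non-negative and sum to 1 within 1e-9")
  }
  length <- as.integer(length)
  if (length < 1L) stop("length must be a positive integer")
  structure(list(abundances = abundances, length = length),
            class = "fc_background_model")
}

#' Natural amino-acid abundances
#'
#' Approximate relative frequencies of the 20 standard amino acids in
#' SwissProt, renormalized to sum to exactly 1. Used as the default
#' composition of the background control model.
#'
#' @return Named numeric vector of length 20.
#' @export
natural_abundances <- function() {
  x <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.46, C = 1.38,
         Q = 3.93, E = 6.72, G = 7.07, H = 2.27, I = 5.91,
         L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.74,
         S = 6.64, T = 5.35, W = 1.10, Y = 2.92, V = 6.86)
  x <- x[AA_ALPHABET]
  x / sum(x)
}
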