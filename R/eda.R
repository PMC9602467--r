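#' Easy Data Augmentation parameters
#'
#' Controls the per-sentence augmentation driver. `alpha` is the fraction
#' of a sentence's tokens perturbed by one operator application (the
#' field's recommended 0.05 is the default; larger values degrade
#' fidelity). `p_delete` is the per-token deletion probability of random
#' deletion and defaults to `alpha`, the usual EDA convention.
#'
#' @param alpha Perturbation fraction in `[0, 1]` (default 0.05).
#' @param p_delete Per-token deletion probability (default `alpha`).
#' @param operator_policy How operators are assigned to augmented copies:
#'   `"CYCLE"` (default; deterministic rotation SR, RI, RS, RD giving
#'   balanced coverage), `"UNIFORM_RANDOM"`, or `"FIXED:<OP>"` (e.g.
#'   `"FIXED:SR"`).
#' @param insertion_mode `"DUPLICATE"` (default: random insertion copies
#'   an existing non-stopword token) or `"SYNONYM"` (the classic EDA
#'   variant: it inserts a synonym of a non-stopword token).
#' @param seed Optional integer seed recorded on the object; drivers that
#'   own randomness (e.g. [balance_augment()]) use it to derive
#'   per-sentence seeds.
#' @return An object of class `eda_params`.
#' @export
eda_params <- function(alpha = 0.05, p_delete = alpha,
                       operator_policy = "CYCLE",
                       insertion_mode = c("DUPLICATE", "SYNONYM"),
                       seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, p_delete >= 0, p_delete <= 1)
  insertion_mode <- match.arg(insertion_mode)
  valid_policy <- operator_policy %in% c("CYCLE", "UNIFORM_RANDOM") ||
    grepl("^FIXED:(SR|RI|RS|RD)$", operator_policy)
  if (!valid_policy) {
    stop("`operator_policy` must be CYCLE, UNIFORM_RANDOM or FIXED:<SR|RI|RS|RD>",
         call. = FALSE)
  }
  structure(
    list(alpha = alpha, p_delete = p_delete,
         operator_policy = operator_policy,
         insertion_mode = insertion_mode, seed = seed),
    class = "eda_params"
  )
}

#' Number of token changes for one operator application
#'
#' `max(1, round(alpha * length))` for nonempty sentences, so every
#' application perturbs at least one token; 0 for empty input.
#'
#' @param length Token count of the sentence.
#' @param alpha Perturbation fraction.
#' @return Integer number of changes.
#' @export
#' @examples
#' n_changes(20, 0.05) # 1
#' n_changes(100, 0.1) # 10
n_changes <- function(length, alpha) {
  stopifnot(length >= 0)
  if (length == 0) return(0L)
  max(1L, as.integer(round(alpha * length)))
}

eligible_sr <- function(tokens, lexicon, stopwords) {
  which(!is_stopword(tokens, stopwords) &
          vapply(tokens, function(t) length(synonyms(lexicon, t)) > 0,
                 logical(1), USE.NAMES = FALSE))
}

#' Synonym replacement
#'
#' Replaces up to `n` tokens by a uniformly chosen synonym each. Eligible
#' targets are non-stopword tokens with a nonempty synonym set; if fewer
#' than `n` exist, all of them are replaced. Token positions are otherwise
#' unchanged.
#'
#' @param tokens Character vector of tokens.
#' @param n Number of replacements requested.
#' @param lexicon A [synonym_lexicon()].
#' @param stopwords A [stopword_list()].
#' @return The perturbed token vector.
#' @export
synonym_replacement <- function(tokens, n, lexicon, stopwords) {
  stopifnot(n >= 0)
  if (n == 0 || length(tokens) == 0) return(tokens)
  eligible <- eligible_sr(tokens, lexicon, stopwords)
  if (length(eligible) == 0) return(tokens)
  targets <- resample(eligible, min(n, length(eligible)))
  for (i in targets) {
    syns <- synonyms(lexicon, tokens[i])
    tokens[i] <- resample(syns, 1)
  }
  tokens
}

#' Random insertion
#'
#' Inserts `n` tokens at uniformly chosen gaps. In `DUPLICATE` mode each
#' inserted token is a copy of a uniformly chosen non-stopword token of
#' the current sentence; in `SYNONYM` mode it is a uniformly chosen
#' synonym of such a token. Stopwords are never inserted. Output length is
#' exactly `length(tokens) + n`; if no eligible source token exists the
#' input is returned unchanged with a warning.
#'
#' @inheritParams synonym_replacement
#' @param mode `"DUPLICATE"` or `"SYNONYM"`.
#' @return The perturbed token vector.
#' @export
random_insertion <- function(tokens, n, lexicon, stopwords,
                             mode = c("DUPLICATE", "SYNONYM")) {
  stopifnot(n >= 0)
  mode <- match.arg(mode)
  if (n == 0) return(tokens)
  if (length(tokens) == 0) {
    warning("random_insertion: empty sentence, nothing to insert")
    return(tokens)
  }
  for (k in seq_len(n)) {
    if (mode == "DUPLICATE") {
      sources <- which(!is_stopword(tokens, stopwords))
      if (length(sources) == 0) {
        warning("random_insertion: no eligible source token; input unchanged")
        return(tokens)
      }
      new_tok <- tokens[resample(sources, 1)]
    } else {
      sources <- eligible_sr(tokens, lexicon, stopwords)
      if (length(sources) == 0) {
        warning("random_insertion: no token with synonyms; input unchanged")
        return(tokens)
      }
      new_tok <- resample(synonyms(lexicon, tokens[resample(sources, 1)]), 1)
    }
    gap <- sample.int(length(tokens) + 1L, 1L) # gap g inserts before position g
    tokens <- append(tokens, new_tok, after = gap - 1L)
  }
  tokens
}

#' Random swap
#'
#' Applies `n` sequential swaps of two uniformly chosen distinct
#' positions. The output is always a permutation of the input; sentences
#' of length 0 or 1 are returned unchanged.
#'
#' @param tokens Character vector of tokens.
#' @param n Number of swaps.
#' @return The permuted token vector.
#' @export
random_swap <- function(tokens, n) {
  stopifnot(n >= 0)
  if (length(tokens) < 2 || n == 0) return(tokens)
  for (k in seq_len(n)) {
    ij <- sample.int(length(tokens), 2L)
    tokens[ij] <- tokens[rev(ij)]
  }
  tokens
}

#' Random deletion
#'
#' Deletes each token independently with probability `p`. A nonempty
#' input never yields an empty output: if every token is deleted, one
#' uniformly chosen token is returned instead.
#'
#' @param tokens Character vector of tokens.
#' @param p Per-token deletion probability in `[0, 1]`.
#' @return The thinned token vector.
#' @export
random_deletion <- function(tokens, p) {
  stopifnot(p >= 0, p <= 1)
  if (length(tokens) == 0) return(tokens)
  keep <- stats::runif(length(tokens)) >= p
  if (!any(keep)) return(resample(tokens, 1))
  tokens[keep]
}

eda_operator_cycle <- function() c("SR", "RI", "RS", "RD")

apply_eda_operator <- function(op, tokens, params, lexicon, stopwords) {
  n <- n_changes(length(tokens), params$alpha)
  switch(op,
    SR = synonym_replacement(tokens, n, lexicon, stopwords),
    RI = random_insertion(tokens, n, lexicon, stopwords, params$insertion_mode),
    RS = random_swap(tokens, n),
    RD = random_deletion(tokens, params$p_delete),
    stop("unknown EDA operator: ", op)
  )
}

#' Augment one original sample into a set of copies
#'
#' Produces `n_out` samples from one original transcript: the original
#' itself first, then `n_out - 1` augmented copies, each produced by
#' exactly one EDA operator chosen by `operator_policy`. Every output row
#' keeps the input's `label`, `task`, `subject_id` and `origin_id`;
#' augmented rows get a fresh `sample_id` and carry the operator's tag.
#' Randomness is drawn from the current RNG state, so callers that need
#' reproducibility wrap the call in a seed (as [balance_augment()] does).
#'
#' @param sample A one-row corpus tibble with `augmentation_tag ==
#'   "ORIGINAL"`.
#' @param params An [eda_params()] object.
#' @param lexicon A [synonym_lexicon()].
#' @param stopwords A [stopword_list()].
#' @param n_out Total number of output samples (original included);
#'   at least 1.
#' @param tokenizer Tokenizer contract used to split and re-join text.
#' @return A corpus tibble of `n_out` rows.
#' @export
augment_sentence <- function(sample, params, lexicon, stopwords, n_out,
                             tokenizer = whitespace_tokenizer()) {
  stopifnot(inherits(params, "eda_params"), n_out >= 1)
  sample <- tibble::as_tibble(sample)
  stopifnot(nrow(sample) == 1)
  if (sample$augmentation_tag != "ORIGINAL") {
    stop("augment_sentence() requires an ORIGINAL sample", call. = FALSE)
  }
  if (n_out == 1) return(sample)
  n_aug <- n_out - 1L
  ops <- switch_policy_ops(params$operator_policy, n_aug)
  tokens <- tokenizer$tokenize(sample$text)
  out <- vector("list", n_aug)
  for (k in seq_len(n_aug)) {
    aug_tokens <- apply_eda_operator(ops[k], tokens, params, lexicon, stopwords)
    row <- sample
    row$sample_id <- paste0(sample$sample_id, "-", tolower(ops[k]), k)
    row$text <- tokenizer$detokenize(aug_tokens)
    row$augmentation_tag <- ops[k]
    out[[k]] <- row
  }
  dplyr::bind_rows(c(list(sample), out))
}

switch_policy_ops <- function(policy, n_aug) {
  if (policy == "CYCLE") {
    rep_len(eda_operator_cycle(), n_aug)
  } else if (policy == "UNIFORM_RANDOM") {
    sample(eda_operator_cycle(), n_aug, replace = TRUE)
  } else {
    rep(sub("^FIXED:", "", policy), n_aug)
  }
}

# sample() with length-1 x means sample.int(x); avoid that trap
resample <- function(x, size) x[sample.int(length(x), size)]
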