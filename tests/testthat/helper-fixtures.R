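# Shared fixtures, built in code.

# A small original-only corpus with explicit rows.
toy_corpus <- function(n_mci = 2, n_hc = 6, text = "alpha bravo charlie delta echo") {
  ids <- c(sprintf("MCI%02d", seq_len(n_mci)), sprintf("HC%02d", seq_len(n_hc)))
  labels <- c(rep("MCI", n_mci), rep("HEALTHY", n_hc))
  mmse <- c(rep(25L, n_mci), rep(29L, n_hc))
  sample_id <- paste0(ids, "-EP1a")
  as_corpus(tibble::tibble(
    sample_id = sample_id, subject_id = ids, task = "EP1a", label = labels,
    text = text, origin_id = sample_id, augmentation_tag = "ORIGINAL",
    mmse = mmse, age = 74, sex = rep_len(c("M", "F"), n_mci + n_hc)
  ))
}

toy_lexicon <- function() {
  synonym_lexicon(list(
    alpha = c("aleph", "ay"), bravo = "bee", charlie = "cee",
    delta = "dee", echo = "ee", dog = "puppy"
  ))
}

toy_stopwords <- function(words = c("the", "alpha")) {
  stopword_list(words, "test")
}

# One fast grid setting for harness tests.
quick_setting <- function(batch_size = 32, learning_rate = 2e-5) {
  grid_configs(hyperparam_grid(batch_sizes = batch_size,
                               learning_rates = learning_rate))[1, ]
}

# A linearly separable corpus: the text names the class.
separable_corpus <- function(n_per_class = 20) {
  n <- 2 * n_per_class
  labels <- rep(c("HEALTHY", "MCI"), each = n_per_class)
  ids <- sprintf("S%02d", seq_len(n))
  sample_id <- paste0(ids, "-EP1a")
  as_corpus(tibble::tibble(
    sample_id = sample_id, subject_id = ids, task = "EP1a", label = labels,
    text = ifelse(labels == "MCI", "mci marker words here", "plain healthy words here"),
    origin_id = sample_id, augmentation_tag = "ORIGINAL",
    mmse = ifelse(labels == "MCI", 25L, 29L), age = 74,
    sex = rep_len(c("M", "F"), n)
  ))
}

# Default fixture resources over the default templates.
default_resources <- function(synonyms_per_word = 3, stopword_fraction = 0.1,
                              seed = 11) {
  vocab <- template_vocabulary(default_task_templates())
  list(lexicon = generate_fixture_lexicon(vocab, synonyms_per_word, seed),
       stopwords = generate_fixture_stopwords(vocab, stopword_fraction))
}
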