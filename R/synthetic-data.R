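#' Cohort specification for the synthetic corpus
#'
#' Describes the study cohort the generator emulates: an imbalanced group
#' of community-dwelling older adults, 45 healthy controls and 15 with
#' mild cognitive impairment, screened by MMSE. Group-conditional MMSE
#' distributions default to the published cohort summary (HC 29.3 +/- 0.7,
#' MCI 25.9 +/- 1.0); sampled scores are rounded and clamped into the
#' label-consistent band ([28, 30] for HC, [23, 27] for MCI) because the
#' summary statistics are conditional on group membership.
#'
#' @param n_healthy,n_mci Subject counts (defaults 45 and 15).
#' @param mmse_mean_hc,mmse_sd_hc,mmse_mean_mci,mmse_sd_mci
#'   Group-conditional MMSE normal parameters, in score units.
#' @param age_mean,age_sd Age distribution in years (defaults 73.7, 4.1).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 45, n_mci = 15,
                        mmse_mean_hc = 29.3, mmse_sd_hc = 0.7,
                        mmse_mean_mci = 25.9, mmse_sd_mci = 1.0,
                        age_mean = 73.7, age_sd = 4.1,
                        seed = 1L) {
  stopifnot(n_healthy >= 0, n_mci >= 0, mmse_sd_hc >= 0, mmse_sd_mci >= 0)
  structure(
    list(n_healthy = as.integer(n_healthy), n_mci = as.integer(n_mci),
         mmse_mean_hc = mmse_mean_hc, mmse_sd_hc = mmse_sd_hc,
         mmse_mean_mci = mmse_mean_mci, mmse_sd_mci = mmse_sd_mci,
         age_mean = age_mean, age_sd = age_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Group-dependent linguistic effects of the synthetic corpus
#'
#' The generator plants the lexical signatures most consistently reported
#' for cognitive decline in spontaneous speech: a higher pronoun rate
#' (vague reference replacing content words), a lower type-token ratio
#' (reduced lexical diversity), and — for the picture and animation tasks —
#' lower coverage of the stimulus's key events. Setting the two groups'
#' parameters equal produces a corpus with no class signal.
#'
#' @param pronoun_rate_hc,pronoun_rate_mci Probability that a content-word
#'   slot holds a pronoun instead (defaults 0.08 and 0.22).
#' @param ttr_hc,ttr_mci Target type-token ratio of the content words
#'   (defaults 0.7 and 0.5).
#' @param event_coverage_hc,event_coverage_mci Fraction of a task's key
#'   events mentioned; applies to tasks with key events (defaults 0.9,
#'   0.6).
#' @param mean_len,len_sd Token count distribution per sample (defaults
#'   80 and 15, roughly a one-to-two-minute monologue after
#'   tokenization).
#' @param filler_rate Expected fillers per content token (default 0.05).
#' @return An object of class `linguistic_effects`.
#' @export
linguistic_effects <- function(pronoun_rate_hc = 0.08, pronoun_rate_mci = 0.22,
                               ttr_hc = 0.7, ttr_mci = 0.5,
                               event_coverage_hc = 0.9,
                               event_coverage_mci = 0.6,
                               mean_len = 80, len_sd = 15,
                               filler_rate = 0.05) {
  rates <- c(pronoun_rate_hc, pronoun_rate_mci, ttr_hc, ttr_mci,
             event_coverage_hc, event_coverage_mci, filler_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), mean_len > 0, len_sd >= 0)
  structure(
    list(pronoun_rate_hc = pronoun_rate_hc,
         pronoun_rate_mci = pronoun_rate_mci,
         ttr_hc = ttr_hc, ttr_mci = ttr_mci,
         event_coverage_hc = event_coverage_hc,
         event_coverage_mci = event_coverage_mci,
         mean_len = mean_len, len_sd = len_sd, filler_rate = filler_rate),
    class = "linguistic_effects"
  )
}

#' Pronoun and filler inventories of the synthetic vocabulary
#'
#' Fixed token sets used by the generator; disjoint from every task's
#' topic vocabulary so that pronoun and filler rates can be measured
#' exactly on generated text.
#'
#' @return Character vector of tokens.
#' @export
pronoun_inventory <- function() {
  c("it", "that", "this", "he", "she", "they", "there", "them")
}

#' @rdname pronoun_inventory
#' @export
filler_inventory <- function() {
  c("um", "uh", "well", "erm", "so")
}

#' Task template
#'
#' One per task: a topic vocabulary of content words and, for the
#' picture/animation description tasks, an ordered list of key-event
#' phrases (each a short token sequence). Episodic templates have no key
#' events — their content varies from subject to subject — and rely on
#' topic vocabulary alone.
#'
#' @param task A task identifier from [task_ids()].
#' @param topic_vocabulary Character vector of content words.
#' @param key_events List of character vectors (ordered event phrases);
#'   empty for episodic tasks, at least 4 for `Picture` and `Animation`.
#' @return An object of class `task_template`.
#' @export
task_template <- function(task, topic_vocabulary, key_events = list()) {
  stopifnot(task %in% task_ids(), length(topic_vocabulary) > 0)
  if (task %in% c("Picture", "Animation") && length(key_events) < 4) {
    stop("`Picture` and `Animation` templates need at least 4 key events",
         call. = FALSE)
  }
  structure(
    list(task = task, topic_vocabulary = as.character(topic_vocabulary),
         key_events = lapply(key_events, as.character)),
    class = "task_template"
  )
}

#' Default task templates
#'
#' Builds one template per task. Topic vocabularies are synthetic tokens
#' (`ep1a_w01`, ...), distinct across tasks and disjoint from the pronoun
#' and filler inventories. The animation template carries the stimulus's
#' four story events (two dogs walking, the encounter with a creature
#' tormenting a smaller one, the surprise rescue, the thank-you ride);
#' the picture template carries four salient scene elements of the
#' kitchen-scene stimulus. Both are rendered as synthetic token phrases.
#'
#' @param n_topic_words Content words per task vocabulary (default 40).
#' @return Named list of 12 [task_template()] objects, keyed by task id.
#' @export
default_task_templates <- function(n_topic_words = 40) {
  stopifnot(n_topic_words >= 1)
  templates <- lapply(task_ids(), function(tk) {
    vocab <- sprintf("%s_w%02d", tolower(tk), seq_len(n_topic_words))
    events <- list()
    if (tk %in% c("Picture", "Animation")) {
      events <- lapply(1:4, function(k) {
        sprintf("%s_event%d_%s", tolower(tk), k, letters[1:3])
      })
    }
    task_template(tk, vocab, events)
  })
  stats::setNames(templates, task_ids())
}

#' Union of the topic vocabularies of a template set
#'
#' @param templates A list of [task_template()] objects.
#' @param include_closed_class Also include the pronoun and filler
#'   inventories (default `TRUE`).
#' @return Character vector of vocabulary tokens.
#' @export
template_vocabulary <- function(templates, include_closed_class = TRUE) {
  vocab <- unique(unlist(lapply(templates, `[[`, "topic_vocabulary")))
  if (include_closed_class) {
    vocab <- unique(c(vocab, pronoun_inventory(), filler_inventory()))
  }
  vocab
}

#' Generate a synthetic cohort
#'
#' Draws `n_healthy + n_mci` subjects with group-conditional MMSE and age.
#' MMSE values are rounded integers clamped into the group's label band so
#' [assign_label()] reproduces the intended group exactly. Sex alternates
#' within group, giving the near-balanced ratio of the emulated cohort.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group`, `mmse`, `age`,
#'   `sex`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    draw_group <- function(n, prefix, mmse_mean, mmse_sd, band) {
      if (n == 0) return(NULL)
      mmse <- pmin(band[2], pmax(band[1], round(stats::rnorm(n, mmse_mean, mmse_sd))))
      tibble::tibble(
        subject_id = sprintf("%s%02d", prefix, seq_len(n)),
        group = if (prefix == "HC") "HEALTHY" else "MCI",
        mmse = as.integer(mmse),
        age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
        sex = rep_len(c("M", "F"), n)
      )
    }
    dplyr::bind_rows(
      draw_group(spec$n_healthy, "HC", spec$mmse_mean_hc, spec$mmse_sd_hc, c(28L, 30L)),
      draw_group(spec$n_mci, "MCI", spec$mmse_mean_mci, spec$mmse_sd_mci, c(23L, 27L))
    )
  })
}

effect_side <- function(effects, label) {
  side <- if (label == "MCI") "mci" else "hc"
  list(
    pronoun_rate = effects[[paste0("pronoun_rate_", side)]],
    ttr = effects[[paste0("ttr_", side)]],
    event_coverage = effects[[paste0("event_coverage_", side)]]
  )
}

#' Generate one synthetic transcript sample
#'
#' Emits one task response for one subject, using the effect parameters of
#' the subject's group. The token sequence is built in four steps:
#' content words are drawn so the realized type-token ratio tracks the
#' group target; each content slot is independently replaced by a pronoun
#' at the group's pronoun rate; fillers are sprinkled in; and, for tasks
#' with key events, `round(coverage * n_events)` event phrases are
#' inserted as contiguous runs in template order. Randomness comes from
#' the current RNG state; [generate_corpus()] owns seeding.
#'
#' @param subject A one-row cohort tibble (see [generate_cohort()]).
#' @param template A [task_template()].
#' @param effects A [linguistic_effects()].
#' @param tokenizer Tokenizer contract used to join tokens.
#' @return A one-row corpus tibble.
#' @export
generate_sample <- function(subject, template, effects,
                            tokenizer = whitespace_tokenizer()) {
  stopifnot(inherits(template, "task_template"),
            inherits(effects, "linguistic_effects"))
  subject <- tibble::as_tibble(subject)
  stopifnot(nrow(subject) == 1)
  label <- assign_label(subject$mmse)
  side <- effect_side(effects, label)

  n_content <- max(1L, round(stats::rnorm(1, effects$mean_len, effects$len_sd)))
  vocab <- template$topic_vocabulary
  n_types <- max(1L, min(length(vocab), round(side$ttr * n_content)))
  pool <- resample(vocab, n_types)
  if (n_content <= n_types) {
    tokens <- pool[seq_len(n_content)]
  } else {
    # every pool type appears at least once, so realized TTR ~= target
    tokens <- resample(c(pool, pool[sample.int(n_types, n_content - n_types,
                                               replace = TRUE)]),
                       n_content)
  }

  is_pron <- stats::runif(n_content) < side$pronoun_rate
  if (any(is_pron)) {
    tokens[is_pron] <- pronoun_inventory()[sample.int(length(pronoun_inventory()),
                                                      sum(is_pron), replace = TRUE)]
  }

  n_fill <- stats::rbinom(1, n_content, effects$filler_rate)
  if (n_fill > 0) {
    fillers <- filler_inventory()[sample.int(length(filler_inventory()),
                                             n_fill, replace = TRUE)]
    gaps <- sort(sample.int(length(tokens) + 1L, n_fill, replace = TRUE))
    for (j in rev(seq_len(n_fill))) {
      tokens <- append(tokens, fillers[j], after = gaps[j] - 1L + (j - 1L))
    }
  }

  n_events <- length(template$key_events)
  if (n_events > 0) {
    k <- round(side$event_coverage * n_events)
    if (k > 0) {
      chosen <- sort(resample(seq_len(n_events), k))
      cuts <- sort(sample.int(length(tokens) + 1L, k, replace = TRUE))
      for (j in rev(seq_len(k))) {
        tokens <- append(tokens, template$key_events[[chosen[j]]],
                         after = cuts[j] - 1L)
      }
    }
  }

  sid <- paste(subject$subject_id, template$task, sep = "-")
  tibble::tibble(
    sample_id = sid,
    subject_id = subject$subject_id,
    task = template$task,
    label = label,
    text = tokenizer$detokenize(tokens),
    origin_id = sid,
    augmentation_tag = "ORIGINAL",
    mmse = subject$mmse,
    age = subject$age,
    sex = subject$sex
  )
}

#' Generate a full synthetic corpus
#'
#' One sample per subject per task. With the default cohort (45 HC, 15
#' MCI) and the 12-task protocol this yields 720 samples, 540 healthy and
#' 180 MCI — the imbalanced structure the augmentation pipeline is built
#' to repair. Deterministic for fixed `seed`.
#'
#' @param spec A [cohort_spec()] (its own seed is ignored here; `seed`
#'   governs the whole corpus).
#' @param effects A [linguistic_effects()].
#' @param templates Named list of 12 templates, one per task id.
#' @param seed Integer seed for cohort and text generation.
#' @return A corpus tibble (see [as_corpus()]).
#' @export
generate_corpus <- function(spec = cohort_spec(),
                            effects = linguistic_effects(),
                            templates = default_task_templates(),
                            seed = spec$seed) {
  missing_tasks <- setdiff(task_ids(), names(templates))
  if (length(missing_tasks) > 0) {
    stop("missing template(s) for task(s): ",
         paste(missing_tasks, collapse = ", "), call. = FALSE)
  }
  if (length(templates) != 12) {
    stop("exactly 12 templates required, one per task", call. = FALSE)
  }
  spec$seed <- derive_seed(seed, 0L)
  cohort <- generate_cohort(spec)
  withr::with_seed(derive_seed(seed, 1L), {
    rows <- vector("list", nrow(cohort) * 12L)
    idx <- 1L
    for (i in seq_len(nrow(cohort))) {
      for (tk in task_ids()) {
        rows[[idx]] <- generate_sample(cohort[i, ], templates[[tk]], effects)
        idx <- idx + 1L
      }
    }
    as_corpus(dplyr::bind_rows(rows))
  })
}

#' Generate a fixture synonym lexicon
#'
#' Stands in for a WordNet-derived synonym table: every vocabulary word
#' maps to `synonyms_per_word` distinct synthetic synonyms (suffixed forms
#' of the word, never the word itself). Deterministic for fixed seed.
#'
#' @param vocabulary Character vector of words.
#' @param synonyms_per_word Synonym count per word (0 makes synonym
#'   replacement the identity).
#' @param seed Integer seed (orders the synonym sets).
#' @return A [synonym_lexicon()].
#' @export
generate_fixture_lexicon <- function(vocabulary, synonyms_per_word, seed = 1L) {
  stopifnot(synonyms_per_word >= 0)
  if (synonyms_per_word == 0) return(synonym_lexicon())
  withr::with_seed(as.integer(seed), {
    mapping <- lapply(stats::setNames(vocabulary, vocabulary), function(w) {
      resample(paste0(w, ".s", seq_len(synonyms_per_word)), synonyms_per_word)
    })
    synonym_lexicon(mapping)
  })
}

#' Generate a fixture stopword list
#'
#' A deterministic subset of the vocabulary (the first `fraction` share in
#' sorted order), standing in for a curated stopword list.
#'
#' @param vocabulary Character vector of words.
#' @param fraction Fraction of the vocabulary to mark as stopwords.
#' @return A [stopword_list()] with `source_name = "fixture"`.
#' @export
generate_fixture_stopwords <- function(vocabulary, fraction = 0.1) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- round(fraction * length(vocabulary))
  stopword_list(utils::head(sort(unique(vocabulary)), n), "fixture")
}

# deterministic per-stage seed fan-out; kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919 + 12345) %% 2147483646L + 1)
}
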