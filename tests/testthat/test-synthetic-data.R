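test_that("generate_cohort reproduces the intended group structure", {
  cohort <- generate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(cohort), 60)
  labels <- assign_label(cohort$mmse)
  expect_equal(sum(labels == "HEALTHY"), 45)
  expect_equal(sum(labels == "MCI"), 15)
  expect_true(all(cohort$mmse[cohort$group == "HEALTHY"] %in% 28:30))
  expect_true(all(cohort$mmse[cohort$group == "MCI"] %in% 23:27))
  expect_false(anyDuplicated(cohort$subject_id) > 0)

  expect_identical(generate_cohort(cohort_spec(seed = 1)), cohort)
  expect_false(identical(generate_cohort(cohort_spec(seed = 2)), cohort))

  one <- generate_cohort(cohort_spec(n_healthy = 0, n_mci = 1, seed = 3))
  expect_equal(nrow(one), 1)
  expect_identical(assign_label(one$mmse), "MCI")
})

test_that("generate_corpus yields one sample per subject per task", {
  corpus <- generate_corpus(seed = 5)
  expect_equal(nrow(corpus), 720)
  expect_equal(sum(corpus$label == "MCI"), 180)
  expect_equal(sum(corpus$label == "HEALTHY"), 540)
  expect_equal(unname(table(corpus$task)[task_ids()]), rep(60L, 12),
               ignore_attr = TRUE)
  expect_true(all(corpus$augmentation_tag == "ORIGINAL"))

  small <- generate_corpus(cohort_spec(n_healthy = 1, n_mci = 0), seed = 5)
  expect_equal(nrow(small), 12)

  expect_error(
    generate_corpus(templates = default_task_templates()[1:11], seed = 5),
    "missing template"
  )
})

test_that("key-event coverage follows the rounding rule, events in order", {
  templates <- default_task_templates()
  anim <- templates[["Animation"]]
  hc <- tibble::tibble(subject_id = "HC01", group = "HEALTHY", mmse = 29L,
                       age = 74, sex = "F")
  mci <- tibble::tibble(subject_id = "MCI01", group = "MCI", mmse = 25L,
                        age = 74, sex = "M")

  full <- linguistic_effects(event_coverage_hc = 1.0, event_coverage_mci = 0.5)
  event_pos <- function(text, template) {
    vapply(template$key_events, function(evt) {
      regexpr(paste(evt, collapse = " "), text, fixed = TRUE)[1]
    }, numeric(1))
  }
  withr::with_seed(6, {
    s_hc <- generate_sample(hc, anim, full)
    pos <- event_pos(s_hc$text, anim)
    expect_true(all(pos > 0)) # all four events present as contiguous phrases
    expect_true(all(diff(pos) > 0)) # in template order

    s_mci <- generate_sample(mci, anim, full)
    expect_equal(sum(event_pos(s_mci$text, anim) > 0), 2) # round(0.5 * 4)
  })
})

test_that("pronoun boundary: rate 1 fills every content slot with a pronoun", {
  ep <- default_task_templates()[["EP1a"]]
  mci <- tibble::tibble(subject_id = "MCI01", group = "MCI", mmse = 24L,
                        age = 74, sex = "M")
  eff <- linguistic_effects(pronoun_rate_mci = 1.0, filler_rate = 0)
  withr::with_seed(7, {
    s <- generate_sample(mci, ep, eff)
    toks <- whitespace_tokenizer()$tokenize(s$text)
    expect_true(all(toks %in% pronoun_inventory()))
    expect_gte(length(toks), 1)
  })
})

test_that("empirical pronoun rates track the group parameters", {
  eff <- linguistic_effects(pronoun_rate_hc = 0.08, pronoun_rate_mci = 0.22,
                            filler_rate = 0)
  ep <- default_task_templates()[["EP2a"]]
  check_group <- function(subject, rate, seed) {
    withr::with_seed(seed, {
      n_pron <- 0; n_slots <- 0
      for (i in 1:220) {
        toks <- whitespace_tokenizer()$tokenize(
          generate_sample(subject, ep, eff)$text)
        n_pron <- n_pron + sum(toks %in% pronoun_inventory())
        n_slots <- n_slots + length(toks)
      }
      se <- sqrt(rate * (1 - rate) / n_slots)
      expect_lt(abs(n_pron / n_slots - rate), 3 * se)
    })
  }
  check_group(tibble::tibble(subject_id = "HC01", group = "HEALTHY",
                             mmse = 29L, age = 74, sex = "F"), 0.08, 21)
  check_group(tibble::tibble(subject_id = "MCI01", group = "MCI",
                             mmse = 25L, age = 74, sex = "M"), 0.22, 22)
})

test_that("lexical separability knob drives held-out accuracy", {
  spec <- cohort_spec(n_healthy = 15, n_mci = 5)
  fast_eff <- function(...) linguistic_effects(mean_len = 30, len_sd = 5, ...)
  # batch size 1 gives the SGD baseline enough updates to exploit any signal
  setting <- quick_setting(batch_size = 1, learning_rate = 5e-5)
  acc_for <- function(effects, seed) {
    corpus <- generate_corpus(spec, effects, seed = seed)
    sp <- make_splits(corpus, split_spec(n_repeats = 1, mode = "ORIGIN_LEVEL",
                                         seed = seed))
    run <- train_eval(corpus, sp[[1]], baseline_backend(), setting,
                      seed = seed)
    mean(run$predictions == run$truth)
  }
  # maximum separation: MCI speaks only in pronouns, HC never does
  sep <- vapply(1:5, function(s) {
    acc_for(fast_eff(pronoun_rate_hc = 0, pronoun_rate_mci = 1), 100 + s)
  }, numeric(1))
  expect_gte(median(sep), 0.98)

  # equal effects: nothing to learn; accuracy indistinguishable from majority
  null_eff <- fast_eff(pronoun_rate_hc = 0.15, pronoun_rate_mci = 0.15,
                       ttr_hc = 0.6, ttr_mci = 0.6,
                       event_coverage_hc = 0.8, event_coverage_mci = 0.8)
  null_acc <- vapply(1:5, function(s) acc_for(null_eff, 200 + s), numeric(1))
  n_test_total <- 5 * round(0.2 * nrow(generate_corpus(spec, null_eff, seed = 1)))
  se <- sqrt(0.75 * 0.25 / n_test_total)
  expect_lt(abs(mean(null_acc) - 0.75), max(3 * se, 0.05))
})

test_that("fixture lexicon and stopwords are deterministic and well-formed", {
  lex <- generate_fixture_lexicon(c("dog", "walk"), 2, seed = 9)
  expect_length(synonyms(lex, "dog"), 2)
  expect_false("dog" %in% synonyms(lex, "dog"))
  expect_identical(generate_fixture_lexicon(c("dog", "walk"), 2, seed = 9), lex)

  empty <- generate_fixture_lexicon(c("dog", "walk"), 0)
  toks <- c("dog", "walk")
  expect_identical(
    withr::with_seed(1, synonym_replacement(toks, 2, empty, stopword_list())),
    toks
  )

  sw <- generate_fixture_stopwords(sprintf("w%02d", 1:20), 0.25)
  expect_length(sw, 5)
  expect_true(all(sw$words %in% sprintf("w%02d", 1:20)))
  expect_identical(generate_fixture_stopwords(sprintf("w%02d", 1:20), 0.25)$words,
                   sw$words)
})

test_that("lexicon and stopword fixtures round-trip through their file dialects", {
  lex <- generate_fixture_lexicon(c("alpha", "bravo"), 3, seed = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_synonyms(lex, p)
  back <- load_synonyms(p)
  expect_setequal(synonyms(back, "alpha"), synonyms(lex, "alpha"))

  sw <- generate_fixture_stopwords(letters, 0.5)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_stopwords(sw, p2)
  expect_setequal(suppressMessages(load_stopwords(p2))$words, sw$words)
})
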