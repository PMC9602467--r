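test_that("n_changes applies the max(1, round(alpha * length)) rule", {
  expect_identical(n_changes(20, 0.05), 1L)
  expect_identical(n_changes(10, 0.05), 1L) # forced up by max(1, .)
  expect_identical(n_changes(100, 0.1), 10L)
  expect_identical(n_changes(0, 0.5), 0L)
  expect_identical(n_changes(1, 0), 1L)
})

test_that("synonym replacement only touches eligible tokens", {
  lex <- synonym_lexicon(list(dog = "puppy"))
  sw <- stopword_list("the")
  withr::with_seed(1, {
    # only "dog" is eligible: "the" is a stopword, "runs" has no synonyms
    expect_identical(synonym_replacement(c("the", "dog", "runs"), 1, lex, sw),
                     c("the", "puppy", "runs"))
    # n = 0 is the identity
    toks <- c("the", "dog", "runs")
    expect_identical(synonym_replacement(toks, 0, lex, sw), toks)
    # all-stopword input unchanged
    expect_identical(synonym_replacement(c("the", "the"), 3, lex,
                                         stopword_list("the")),
                     c("the", "the"))
    # more requested changes than eligible tokens: all eligible replaced
    expect_identical(synonym_replacement(c("dog", "cat"), 5, lex, sw),
                     c("puppy", "cat"))
  })
})

test_that("random insertion grows the sentence by n and never inserts stopwords", {
  lex <- toy_lexicon()
  sw <- stopword_list("the")
  withr::with_seed(2, {
    expect_identical(random_insertion("dog", 1, lex, sw, "DUPLICATE"),
                     c("dog", "dog"))
    toks <- c("the", "dog")
    expect_identical(random_insertion(toks, 0, lex, sw), toks)

    out <- random_insertion(c("the", "dog"), 2, lex, sw, "DUPLICATE")
    expect_length(out, 4)
    expect_identical(sort(out), c("dog", "dog", "dog", "the"))

    # no eligible source: unchanged with a warning
    expect_warning(
      out2 <- random_insertion(c("the", "the"), 1, lex, sw, "DUPLICATE"),
      "no eligible"
    )
    expect_identical(out2, c("the", "the"))

    # SYNONYM mode inserts a synonym of a non-stopword token
    out3 <- random_insertion(c("the", "dog"), 1, lex, sw, "SYNONYM")
    expect_length(out3, 3)
    expect_true(setdiff(out3, c("the", "dog")) %in% synonyms(lex, "dog"))
  })
})

test_that("random swap permutes and random deletion never empties", {
  withr::with_seed(3, {
    expect_identical(random_swap(c("a", "b"), 1), c("b", "a"))
    expect_identical(random_swap("a", 5), "a")
    for (i in 1:20) {
      toks <- sample(letters, sample(2:15, 1), replace = TRUE)
      expect_identical(sort(random_swap(toks, sample(0:5, 1))), sort(toks))
    }

    toks <- c("a", "b", "c")
    expect_identical(random_deletion(toks, 0), toks)
    out <- random_deletion(toks, 1)
    expect_length(out, 1)
    expect_true(out %in% toks)
    # deletion output is always a sub-multiset of the input
    for (i in 1:20) {
      toks <- sample(letters[1:5], 12, replace = TRUE)
      out <- random_deletion(toks, 0.5)
      expect_true(all(table(out) <= table(toks)[names(table(out))]))
    }
  })
})

test_that("random deletion mean output length matches the binomial expectation", {
  # length 20 at p = 0.3: survivors ~ Binomial(20, 0.7); the never-empty
  # adjustment adds P(all deleted) * 1 = 0.3^20, numerically negligible.
  n_len <- 20; p <- 0.3; trials <- 10000
  expected <- n_len * (1 - p) + p^n_len
  se <- sqrt(n_len * p * (1 - p)) / sqrt(trials)
  withr::with_seed(4, {
    lens <- replicate(trials, length(random_deletion(letters[1:n_len], p)))
  })
  expect_lt(abs(mean(lens) - expected), 3 * se)
})

test_that("operators and driver are deterministic under a fixed seed", {
  lex <- toy_lexicon()
  sw <- toy_stopwords("the")
  toks <- c("the", "dog", "bravo", "charlie", "delta", "echo")
  a <- withr::with_seed(9, list(
    synonym_replacement(toks, 2, lex, sw),
    random_insertion(toks, 2, lex, sw),
    random_swap(toks, 2),
    random_deletion(toks, 0.3)
  ))
  b <- withr::with_seed(9, list(
    synonym_replacement(toks, 2, lex, sw),
    random_insertion(toks, 2, lex, sw),
    random_swap(toks, 2),
    random_deletion(toks, 0.3)
  ))
  expect_identical(a, b)
  # distinct seeds give distinct outputs with high probability on longer input
  many_a <- withr::with_seed(10, replicate(10, paste(random_swap(toks, 2), collapse = " ")))
  many_b <- withr::with_seed(11, replicate(10, paste(random_swap(toks, 2), collapse = " ")))
  expect_false(identical(many_a, many_b))
})

test_that("augment_sentence emits the original plus operator-tagged copies", {
  corp <- toy_corpus(n_mci = 1, n_hc = 0)
  lex <- toy_lexicon()
  sw <- toy_stopwords("the")
  params <- eda_params()

  expect_identical(
    withr::with_seed(5, augment_sentence(corp[1, ], params, lex, sw, 1)),
    corp[1, ]
  )

  out <- withr::with_seed(5, augment_sentence(corp[1, ], params, lex, sw, 30))
  expect_equal(nrow(out), 30)
  expect_identical(out$augmentation_tag[1], "ORIGINAL")
  expect_identical(out$augmentation_tag[-1],
                   rep_len(c("SR", "RI", "RS", "RD"), 29))
  # label/task/subject/origin conservation
  expect_true(all(out$label == corp$label[1]))
  expect_true(all(out$task == corp$task[1]))
  expect_true(all(out$subject_id == corp$subject_id[1]))
  expect_true(all(out$origin_id == corp$sample_id[1]))
  expect_false(anyDuplicated(out$sample_id) > 0)

  out2 <- withr::with_seed(5, augment_sentence(corp[1, ], params, lex, sw, 30))
  expect_identical(out, out2)
})

test_that("augment_sentence respects operator policies", {
  corp <- toy_corpus(n_mci = 1, n_hc = 0)
  lex <- toy_lexicon()
  sw <- toy_stopwords("the")

  fixed <- withr::with_seed(6, augment_sentence(
    corp[1, ], eda_params(operator_policy = "FIXED:RS"), lex, sw, 5))
  expect_identical(fixed$augmentation_tag[-1], rep("RS", 4))

  unif <- withr::with_seed(6, augment_sentence(
    corp[1, ], eda_params(operator_policy = "UNIFORM_RANDOM"), lex, sw, 40))
  expect_true(all(unif$augmentation_tag[-1] %in% c("SR", "RI", "RS", "RD")))

  expect_error(eda_params(operator_policy = "FIXED:XX"), "operator_policy")
  expect_error(
    augment_sentence(dplyr::mutate(corp[1, ], augmentation_tag = "SR",
                                   origin_id = "other"),
                     eda_params(), lex, sw, 2),
    "ORIGINAL"
  )
})

test_that("stopword protection and edit bounds hold across random cases", {
  vocab <- sprintf("w%02d", 1:30)
  lex <- generate_fixture_lexicon(vocab, 2, seed = 7)
  sw <- stopword_list(vocab[1:6])
  withr::with_seed(8, {
    for (i in 1:30) {
      toks <- sample(vocab, sample(5:25, 1), replace = TRUE)
      n <- sample(1:4, 1)

      sr <- synonym_replacement(toks, n, lex, sw)
      changed <- which(sr != toks)
      expect_lte(length(changed), n)
      expect_false(any(toks[changed] %in% sw$words)) # stopwords untouched
      expect_length(sr, length(toks))

      ri <- random_insertion(toks, n, lex, sw, "DUPLICATE")
      expect_length(ri, length(toks) + n)
      inserted <- ri[-match(toks, ri)] # multiset difference remainder
      tab_in <- table(factor(toks, unique(ri)))
      tab_out <- table(factor(ri, unique(ri)))
      expect_true(all(tab_out >= tab_in)) # output multiset contains input
      extra <- rep(names(tab_out), tab_out - tab_in)
      expect_false(any(extra %in% sw$words)) # never inserts a stopword
    }
  })
})
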