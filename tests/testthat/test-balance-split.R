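test_that("balance_augment multiplies each class by its multiplier", {
  corp <- toy_corpus(n_mci = 2, n_hc = 6)
  plan <- augmentation_plan(multiplier_mci = 3, multiplier_hc = 1,
                            eda = eda_params(seed = 1))
  out <- balance_augment(corp, plan, toy_lexicon(), toy_stopwords())
  expect_equal(nrow(out), 2 * 3 + 6 * 1)
  expect_equal(sum(out$label == "MCI"), 6)
  expect_equal(sum(out$label == "HEALTHY"), 6)

  # both multipliers 1: output equals input
  unit <- augmentation_plan(1, 1, eda_params(seed = 1))
  expect_equal(
    as.data.frame(balance_augment(corp, unit, toy_lexicon(), toy_stopwords())),
    as.data.frame(corp)
  )

  # reproducible, and multiplier arithmetic holds row-by-row
  out2 <- balance_augment(corp, plan, toy_lexicon(), toy_stopwords())
  expect_identical(out, out2)
  per_origin <- table(out$origin_id)
  expect_true(all(per_origin[startsWith(names(per_origin), "MCI")] == 3))

  excluded <- corp
  excluded$label[1] <- "EXCLUDED_DEMENTIA_RANGE"
  excluded$mmse[1] <- 20L
  expect_error(balance_augment(excluded, plan, toy_lexicon(), toy_stopwords()),
               "EXCLUDED")
})

test_that("include_original = FALSE adds the original on top of the multiplier", {
  corp <- toy_corpus(n_mci = 1, n_hc = 1)
  plan <- augmentation_plan(2, 2, eda_params(seed = 1), include_original = FALSE)
  out <- balance_augment(corp, plan, toy_lexicon(), toy_stopwords())
  expect_equal(nrow(out), 2 * 3)
  expect_equal(sum(out$augmentation_tag == "ORIGINAL"), 2)
})

test_that("splits partition the dataset with stratified part sizes", {
  corp <- toy_corpus(n_mci = 10, n_hc = 30, text = "a b c")
  aug <- balance_augment(corp, augmentation_plan(3, 1, eda_params(seed = 2)),
                         toy_lexicon(), toy_stopwords())
  n <- nrow(aug) # 60
  spec <- split_spec(test_fraction = 0.2, validation_fraction = 0.1,
                     n_repeats = 10, seed = 4)
  splits <- make_splits(aug, spec)
  expect_length(splits, 10)
  expect_gt(length(unique(vapply(splits, function(s) paste(s$test, collapse = ","),
                                 character(1)))), 1)
  global <- mean(aug$label == "MCI")
  for (s in splits) {
    expect_length(s$test, round(0.2 * n))
    expect_length(s$validation, round(0.1 * n))
    all_idx <- c(s$train, s$validation, s$test)
    expect_identical(sort(all_idx), seq_len(n)) # exact partition
    for (part in s) {
      # per-part class proportion within one sample of the global proportion
      expect_lte(abs(sum(aug$label[part] == "MCI") - global * length(part)), 1)
    }
  }
})

test_that("origin- and subject-level splits keep groups on one side", {
  corp <- toy_corpus(n_mci = 6, n_hc = 18, text = "a b c d")
  aug <- balance_augment(corp, augmentation_plan(3, 1, eda_params(seed = 3)),
                         toy_lexicon(), toy_stopwords())
  for (mode in c("ORIGIN_LEVEL", "SUBJECT_LEVEL")) {
    splits <- make_splits(aug, split_spec(n_repeats = 3, mode = mode, seed = 5))
    col <- if (mode == "ORIGIN_LEVEL") "origin_id" else "subject_id"
    for (s in splits) {
      expect_identical(sort(unname(unlist(s))), seq_len(nrow(aug)))
      expect_length(intersect(aug[[col]][s$test], aug[[col]][s$train]), 0)
      audit <- leakage_audit(s, aug)
      key <- if (mode == "ORIGIN_LEVEL") "origin_overlap_frac" else "subject_overlap_frac"
      expect_identical(audit[[key]], 0)
    }
  }
})

test_that("grouped stratification fails loudly when a group exceeds the test quota", {
  corp <- toy_corpus(n_mci = 1, n_hc = 3)
  aug <- balance_augment(corp, augmentation_plan(30, 10, eda_params(seed = 6)),
                         toy_lexicon(), toy_stopwords())
  # the single MCI origin has 30 samples; its class test quota is 6
  expect_error(
    make_splits(aug, split_spec(n_repeats = 1, mode = "ORIGIN_LEVEL", seed = 1)),
    "infeasible"
  )
})

test_that("sample-level origin leakage matches the hypergeometric enumeration", {
  # 12 origins x 3 copies, one class; 20% test (7), 10% validation (4),
  # train 25. For a test sample, the chance that none of its 2 sibling
  # copies lands in train is C(10,2)/C(35,2); overlap is the complement.
  corp <- toy_corpus(n_mci = 0, n_hc = 12, text = "a b c d e")
  aug <- balance_augment(corp, augmentation_plan(30, 3, eda_params(seed = 7)),
                         toy_lexicon(), toy_stopwords())
  n <- nrow(aug); n_train <- n - round(0.2 * n) - round(0.1 * n)
  expected <- 1 - choose(n - 1 - n_train, 2) / choose(n - 1, 2)

  splits <- make_splits(aug, split_spec(n_repeats = 200, seed = 8))
  fracs <- vapply(splits, function(s) leakage_audit(s, aug)$origin_overlap_frac,
                  numeric(1))
  # per-split fractions average 7 draws; compare the grand mean
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 4 * se + 1e-8)
})

test_that("splits serialize to JSON and resolve back by sample id", {
  corp <- toy_corpus(n_mci = 4, n_hc = 12, text = "a b c")
  splits <- make_splits(corp, split_spec(n_repeats = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_splits_json(splits, corp, path)
  back <- read_splits_json(path, corp)
  expect_equal(back[[1]]$test, splits[[1]]$test)
  expect_equal(back[[2]]$train, splits[[2]]$train)
})
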