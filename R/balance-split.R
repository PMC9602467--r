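#' Class-balanced augmentation plan
#'
#' Per-class multipliers for oversampling-by-augmentation. A multiplier is
#' the total number of copies each original expands to, the original
#' included; the defaults (30 for the minority MCI class, 10 for the
#' healthy majority) turn a 180/540 corpus into 5,400 samples per class.
#'
#' @param multiplier_mci,multiplier_hc Copies per original, >= 1
#'   (defaults 30 and 10).
#' @param eda An [eda_params()] object governing the operators.
#' @param include_original If `FALSE`, multipliers count augmented copies
#'   only and the original is emitted in addition (default `TRUE`:
#'   multiplier = total copies).
#' @return An object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(multiplier_mci = 30, multiplier_hc = 10,
                              eda = eda_params(), include_original = TRUE) {
  stopifnot(multiplier_mci >= 1, multiplier_hc >= 1,
            inherits(eda, "eda_params"))
  structure(
    list(multiplier_mci = as.integer(multiplier_mci),
         multiplier_hc = as.integer(multiplier_hc),
         eda = eda, include_original = isTRUE(include_original)),
    class = "augmentation_plan"
  )
}

#' Balance a corpus by per-class augmentation
#'
#' Expands every original sample into its class's multiplier of copies
#' via [augment_sentence()]. With the default synthetic corpus (180 MCI
#' and 540 healthy originals) and the default plan this yields 5,400
#' samples per class, 10,800 in total, exactly balanced. Each original's
#' augmentation stream gets its own seed derived from `plan$eda$seed`, so
#' the result is reproducible and independent of corpus order.
#'
#' @param corpus A corpus tibble of ORIGINAL samples with labels
#'   `HEALTHY`/`MCI` only.
#' @param plan An [augmentation_plan()].
#' @param lexicon A [synonym_lexicon()].
#' @param stopwords A [stopword_list()].
#' @param tokenizer Tokenizer contract.
#' @return The augmented corpus tibble.
#' @export
balance_augment <- function(corpus, plan, lexicon, stopwords,
                            tokenizer = whitespace_tokenizer()) {
  stopifnot(inherits(plan, "augmentation_plan"))
  corpus <- as_corpus(corpus)
  if (any(corpus$label == "EXCLUDED_DEMENTIA_RANGE")) {
    stop("corpus contains EXCLUDED_DEMENTIA_RANGE samples; remove them first",
         call. = FALSE)
  }
  if (!all(corpus$augmentation_tag == "ORIGINAL")) {
    stop("balance_augment() expects un-augmented originals", call. = FALSE)
  }
  base_seed <- if (is.null(plan$eda$seed)) 1L else as.integer(plan$eda$seed)
  extra <- if (plan$include_original) 0L else 1L
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    mult <- if (corpus$label[i] == "MCI") plan$multiplier_mci else plan$multiplier_hc
    out[[i]] <- withr::with_seed(
      derive_seed(base_seed, i),
      augment_sentence(corpus[i, ], plan$eda, lexicon, stopwords,
                       n_out = mult + extra, tokenizer = tokenizer)
    )
  }
  as_corpus(dplyr::bind_rows(out))
}

#' Split specification
#'
#' Repeated stratified random splits into train/validation/test. The
#' defaults mirror the evaluation protocol the package replicates: 10
#' repeats, 20% test, 10% validation, stratified by label.
#'
#' Three grouping modes control what is kept on one side of a split:
#' `SAMPLE_LEVEL` assigns augmented samples independently (the protocol
#' being replicated — augmented siblings of a training sentence can land
#' in test, which inflates scores), `ORIGIN_LEVEL` keeps all copies of an
#' original together, and `SUBJECT_LEVEL` keeps all samples of a subject
#' together. The leakage-safe modes are the recommended scientific
#' choice; [leakage_audit()] quantifies the difference.
#'
#' @param test_fraction,validation_fraction Fractions in (0, 1) with sum
#'   below 1 (defaults 0.20 and 0.10).
#' @param n_repeats Number of independent splits (default 10).
#' @param mode `"SAMPLE_LEVEL"`, `"ORIGIN_LEVEL"` or `"SUBJECT_LEVEL"`.
#' @param seed Integer seed; repeat `r` uses a seed derived from it.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.20, validation_fraction = 0.10,
                       n_repeats = 10,
                       mode = c("SAMPLE_LEVEL", "ORIGIN_LEVEL", "SUBJECT_LEVEL"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1,
            test_fraction + validation_fraction < 1,
            n_repeats >= 1)
  structure(
    list(test_fraction = test_fraction,
         validation_fraction = validation_fraction,
         n_repeats = as.integer(n_repeats), mode = mode,
         seed = as.integer(seed)),
    class = "split_spec"
  )
}

# largest-remainder allocation of a total across strata, proportional to sizes
allocate_quota <- function(sizes, total) {
  raw <- sizes / sum(sizes) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

split_one <- function(dataset, spec, rep_seed) {
  n <- nrow(dataset)
  n_test <- round(spec$test_fraction * n)
  n_val <- round(spec$validation_fraction * n)
  classes <- sort(unique(dataset$label))
  group_col <- switch(spec$mode,
    SAMPLE_LEVEL = "sample_id", ORIGIN_LEVEL = "origin_id",
    SUBJECT_LEVEL = "subject_id")
  withr::with_seed(rep_seed, {
    class_sizes <- vapply(classes, function(cl) sum(dataset$label == cl), numeric(1))
    q_test <- allocate_quota(class_sizes, n_test)
    q_val <- allocate_quota(class_sizes, n_val)
    test <- integer(0); val <- integer(0); train <- integer(0)
    for (ci in seq_along(classes)) {
      idx <- which(dataset$label == classes[ci])
      if (spec$mode == "SAMPLE_LEVEL") {
        idx <- idx[sample.int(length(idx))]
        test <- c(test, idx[seq_len(q_test[ci])])
        val <- c(val, idx[q_test[ci] + seq_len(q_val[ci])])
        train <- c(train, idx[-(seq_len(q_test[ci] + q_val[ci]))])
      } else {
        groups <- split(idx, dataset[[group_col]][idx])
        sizes <- lengths(groups)
        if (q_test[ci] > 0 && min(sizes) > q_test[ci]) {
          stop("infeasible ", spec$mode, " stratification: smallest group (",
               min(sizes), " samples) exceeds the class test quota (",
               q_test[ci], ")", call. = FALSE)
        }
        groups <- groups[sample.int(length(groups))]
        part <- rep("train", length(groups))
        fill <- function(part, want, tag) {
          got <- 0
          for (g in seq_along(groups)) {
            if (part[g] != "train") next
            if (got + length(groups[[g]]) <= want) {
              part[g] <- tag
              got <- got + length(groups[[g]])
            }
            if (got >= want) break
          }
          part
        }
        part <- fill(part, q_test[ci], "test")
        part <- fill(part, q_val[ci], "val")
        test <- c(test, unlist(groups[part == "test"], use.names = FALSE))
        val <- c(val, unlist(groups[part == "val"], use.names = FALSE))
        train <- c(train, unlist(groups[part == "train"], use.names = FALSE))
      }
    }
    list(train = sort(train), validation = sort(val), test = sort(test))
  })
}

#' Make repeated stratified train/validation/test splits
#'
#' Returns `spec$n_repeats` index triples over the rows of `dataset`.
#' Each triple partitions the dataset exactly; test and validation sizes
#' are `round(fraction * N)` (grouped modes come as close as whole groups
#' allow), stratified by label via largest-remainder allocation.
#'
#' @param dataset A corpus tibble.
#' @param spec A [split_spec()].
#' @return A list of `n_repeats` lists with integer elements `train`,
#'   `validation`, `test`; the spec is attached as attribute `"spec"`.
#' @export
make_splits <- function(dataset, spec) {
  stopifnot(inherits(spec, "split_spec"))
  dataset <- as_corpus(dataset)
  if (nrow(dataset) == 0) stop("`dataset` is empty", call. = FALSE)
  splits <- lapply(seq_len(spec$n_repeats), function(r) {
    split_one(dataset, spec, derive_seed(spec$seed, r))
  })
  attr(splits, "spec") <- spec
  splits
}

#' Audit a split for augmentation and subject leakage
#'
#' Counts the test samples whose `origin_id` (respectively `subject_id`)
#' also occurs in the training part. Under sample-level splitting of an
#' augmented dataset nearly every test sample shares an origin with
#' training data; origin- and subject-level splits are leak-free by
#' construction.
#'
#' @param split One index triple from [make_splits()].
#' @param dataset The corpus tibble the split indexes.
#' @return A list with `origin_overlap_n`, `origin_overlap_frac`,
#'   `subject_overlap_n`, `subject_overlap_frac`, and `n_test`.
#' @export
leakage_audit <- function(split, dataset) {
  dataset <- tibble::as_tibble(dataset)
  n_test <- length(split$test)
  overlap <- function(col) {
    hit <- dataset[[col]][split$test] %in% dataset[[col]][split$train]
    list(n = sum(hit), frac = if (n_test == 0) 0 else mean(hit))
  }
  o <- overlap("origin_id"); s <- overlap("subject_id")
  list(origin_overlap_n = o$n, origin_overlap_frac = o$frac,
       subject_overlap_n = s$n, subject_overlap_frac = s$frac,
       n_test = n_test)
}

#' Serialize splits to a JSON index file
#'
#' Splits are written keyed by `sample_id` with the spec and seed
#' embedded, so a split can be re-applied to a re-loaded dataset.
#'
#' @param splits Result of [make_splits()].
#' @param dataset The corpus tibble the splits index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splits_json <- function(splits, dataset, path) {
  spec <- attr(splits, "spec")
  payload <- list(
    spec = unclass(spec),
    splits = lapply(splits, function(tr) {
      lapply(tr, function(ix) dataset$sample_id[ix])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
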