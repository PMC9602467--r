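#' Task identifiers of the elicitation protocol
#'
#' The corpus design elicits twelve short monologues per subject: ten
#' episodic-recall prompts (`EP1a` ... `EP8a`, e.g. "a recent sad event",
#' "people you admire"), one picture-description task (`Picture`, the
#' Cookie Theft stimulus) and one animation-description task (`Animation`,
#' a short cartoon with four key story events).
#'
#' @return Character vector of the 12 task identifiers, in protocol order.
#' @export
#' @examples
#' task_ids()
task_ids <- function() {
  c("EP1a", "EP1b", "EP2a", "EP3a", "EP4a", "EP5a",
    "EP6a", "EP6b", "EP7a", "EP8a", "Picture", "Animation")
}

#' Cognitive labels
#'
#' The three labels a subject can receive from the MMSE screening rule:
#' `HEALTHY`, `MCI` (mild cognitive impairment), and
#' `EXCLUDED_DEMENTIA_RANGE` for scores in the possible-dementia band,
#' which never enters a classification dataset.
#'
#' @return Character vector of the three label values.
#' @export
cognitive_labels <- function() {
  c("HEALTHY", "MCI", "EXCLUDED_DEMENTIA_RANGE")
}

#' Augmentation provenance tags
#'
#' @return Character vector of the five provenance tags: `ORIGINAL` plus
#'   one tag per augmentation operator (`SR` synonym replacement, `RI`
#'   random insertion, `RS` random swap, `RD` random deletion).
#' @export
augmentation_tags <- function() {
  c("ORIGINAL", "SR", "RI", "RS", "RD")
}

#' Assign a cognitive label from an MMSE score
#'
#' Applies the screening rule used throughout the package: a Mini-Mental
#' State Examination score of 28-30 is labeled `HEALTHY`, 23-27 is labeled
#' `MCI`, and scores below 23 fall in the possible-dementia range and are
#' labeled `EXCLUDED_DEMENTIA_RANGE` (such subjects are excluded from
#' binary classification).
#'
#' @param mmse Integer vector of MMSE scores; every value must lie in
#'   0-30, the instrument's range.
#' @return Character vector of labels, one per score.
#' @export
#' @examples
#' assign_label(c(29, 27, 23, 22))
assign_label <- function(mmse) {
  if (length(mmse) == 0) return(character(0))
  if (anyNA(mmse) || !is.numeric(mmse)) {
    stop("`mmse` must be numeric with no missing values", call. = FALSE)
  }
  if (any(mmse != round(mmse))) {
    stop("`mmse` must contain integer scores", call. = FALSE)
  }
  if (any(mmse < 0 | mmse > 30)) {
    stop("MMSE scores must lie in [0, 30]", call. = FALSE)
  }
  ifelse(mmse >= 28, "HEALTHY", ifelse(mmse >= 23, "MCI", "EXCLUDED_DEMENTIA_RANGE"))
}

#' Whitespace tokenizer
#'
#' The default tokenizer contract: a pair of functions mapping a raw
#' string to a token vector and back. Tokenization followed by joining is
#' idempotent on its own output, which is all downstream stages require.
#' Corpora of unsegmented text (e.g. Japanese) should be pre-segmented by
#' a morphological analyzer into whitespace-delimited tokens before
#' entering the pipeline, or supply their own tokenizer with the same
#' contract.
#'
#' @return A list with elements `tokenize` (string -> character vector)
#'   and `detokenize` (character vector -> string).
#' @export
#' @examples
#' tok <- whitespace_tokenizer()
#' tok$tokenize("a  b c")
#' tok$detokenize(c("a", "b", "c"))
whitespace_tokenizer <- function() {
  list(
    tokenize = function(x) {
      stopifnot(is.character(x), length(x) == 1)
      x <- trimws(x)
      if (!nzchar(x)) return(character(0))
      strsplit(x, "[[:space:]]+")[[1]]
    },
    detokenize = function(tokens) paste(tokens, collapse = " ")
  )
}

#' Clean a raw transcript
#'
#' Cleansing applied to every transcript before augmentation or
#' classification: recording start/end markers are removed wherever they
#' occur, arbitrary line breaks are collapsed to spaces, and the text is
#' truncated to at most `max_len` tokenizer units (keeping the prefix),
#' matching the input limit of sentence encoders. Cleaning is idempotent.
#'
#' @param raw Character vector of raw transcripts.
#' @param recording_markers Character vector of literal marker strings to
#'   strip (corpus-specific; empty by default).
#' @param max_len Maximum number of tokenizer units retained (default 512).
#' @param tokenizer Tokenizer contract; see [whitespace_tokenizer()].
#' @return Character vector of cleaned transcripts. An empty result is
#'   legal (and signalled with a message) when a transcript contains only
#'   markers and whitespace.
#' @export
#' @examples
#' clean_transcript("<START> I went shopping <END>", c("<START>", "<END>"))
#' clean_transcript("a b\nc")
clean_transcript <- function(raw, recording_markers = character(),
                             max_len = 512L,
                             tokenizer = whitespace_tokenizer()) {
  stopifnot(is.character(raw))
  if (!is.numeric(max_len) || length(max_len) != 1 || max_len <= 0) {
    stop("`max_len` must be a single positive number", call. = FALSE)
  }
  out <- raw
  for (m in recording_markers) {
    out <- gsub(m, " ", out, fixed = TRUE)
  }
  out <- gsub("[\r\n]+", " ", out)
  out <- vapply(out, function(x) {
    toks <- tokenizer$tokenize(x)
    if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
    tokenizer$detokenize(toks)
  }, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(out))) {
    message(sum(!nzchar(out)), " transcript(s) empty after cleansing")
  }
  out
}

corpus_columns <- function() {
  c("sample_id", "subject_id", "task", "label", "text",
    "origin_id", "augmentation_tag", "mmse", "age", "sex")
}

#' Construct and validate a transcript corpus
#'
#' A corpus is a tibble with one row per transcript sample and columns
#' `sample_id`, `subject_id`, `task`, `label`, `text`, `origin_id`,
#' `augmentation_tag`, `mmse`, `age`, `sex`. `origin_id` points to the
#' un-augmented sample a row descends from; for original rows it equals
#' `sample_id` and `augmentation_tag` is `"ORIGINAL"`.
#'
#' @param x A data frame with the corpus columns.
#' @return The validated corpus as a tibble.
#' @export
as_corpus <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(corpus_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("corpus is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, c(corpus_columns(), setdiff(names(x), corpus_columns()))]
  if (anyDuplicated(x$sample_id)) {
    stop("`sample_id` must be unique within a corpus", call. = FALSE)
  }
  if (!all(x$task %in% task_ids())) {
    stop("unknown task identifier(s) in corpus", call. = FALSE)
  }
  if (!all(x$label %in% cognitive_labels())) {
    stop("unknown label(s) in corpus", call. = FALSE)
  }
  if (!all(x$augmentation_tag %in% augmentation_tags())) {
    stop("unknown augmentation tag(s) in corpus", call. = FALSE)
  }
  is_orig <- x$augmentation_tag == "ORIGINAL"
  if (!all(x$origin_id[is_orig] == x$sample_id[is_orig])) {
    stop("ORIGINAL samples must have origin_id == sample_id", call. = FALSE)
  }
  if (any(x$origin_id[!is_orig] == x$sample_id[!is_orig])) {
    stop("augmented samples must not reuse their origin's sample_id", call. = FALSE)
  }
  consistent <- x |>
    dplyr::summarise(
      ok = dplyr::n_distinct(.data$label) == 1 &&
        dplyr::n_distinct(.data$task) == 1 &&
        dplyr::n_distinct(.data$subject_id) == 1,
      .by = "origin_id"
    )
  if (!all(consistent$ok)) {
    stop("label, task and subject_id must be constant within an origin_id",
         call. = FALSE)
  }
  x
}

#' Read and write corpora as JSON lines
#'
#' One sample per line, all fields inline; UTF-8. This is the dialect used
#' for augmented datasets and pipeline artifacts because it preserves the
#' provenance fields and round-trips exactly.
#'
#' @param corpus A corpus tibble (see [as_corpus()]).
#' @param path File path.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns the corpus tibble.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  corpus <- as_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(as.list(corpus[i, corpus_columns()]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l, simplifyVector = TRUE))
  })
  as_corpus(dplyr::bind_rows(rows))
}

#' Read and write corpora as a metadata table plus text files
#'
#' The on-disk layout used for raw corpora: a tab-separated `metadata.tsv`
#' (`subject_id`, `task`, `mmse`, `age`, `sex`, `path`) and one UTF-8
#' plain-text file per sample, relative to the metadata file. Labels are
#' re-derived from MMSE on read; only original (un-augmented) samples use
#' this layout.
#'
#' @param corpus A corpus tibble of ORIGINAL samples.
#' @param dir Directory to write into (created if needed).
#' @param metadata_path Path to a `metadata.tsv` written by
#'   `write_corpus_dir()`.
#' @return `write_corpus_dir()` returns `dir` invisibly;
#'   `read_corpus_dir()` returns the corpus tibble.
#' @export
write_corpus_dir <- function(corpus, dir) {
  corpus <- as_corpus(corpus)
  if (!all(corpus$augmentation_tag == "ORIGINAL")) {
    stop("the directory dialect stores original samples only", call. = FALSE)
  }
  dir.create(file.path(dir, "text"), recursive = TRUE, showWarnings = FALSE)
  rel <- file.path("text", paste0(corpus$sample_id, ".txt"))
  for (i in seq_len(nrow(corpus))) {
    writeLines(corpus$text[i], file.path(dir, rel[i]), useBytes = TRUE)
  }
  meta <- tibble::tibble(
    subject_id = corpus$subject_id, task = corpus$task,
    mmse = corpus$mmse, age = corpus$age, sex = corpus$sex, path = rel
  )
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' @rdname write_corpus_dir
#' @export
read_corpus_dir <- function(metadata_path) {
  if (dir.exists(metadata_path)) {
    metadata_path <- file.path(metadata_path, "metadata.tsv")
  }
  base <- dirname(metadata_path)
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  text <- vapply(meta$path, function(p) {
    paste(readLines(file.path(base, p), encoding = "UTF-8"), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  sample_id <- sub("\\.txt$", "", basename(meta$path))
  as_corpus(tibble::tibble(
    sample_id = sample_id,
    subject_id = as.character(meta$subject_id),
    task = meta$task,
    label = assign_label(meta$mmse),
    text = text,
    origin_id = sample_id,
    augmentation_tag = "ORIGINAL",
    mmse = as.integer(meta$mmse),
    age = as.numeric(meta$age),
    sex = as.character(meta$sex)
  ))
}
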