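#' Construct a synonym lexicon
#'
#' A synonym lexicon maps a word to a nonempty set of synonyms. Self-maps
#' are dropped at construction; looking up an absent word yields the empty
#' set. Real deployments load a WordNet-derived table with
#' [load_synonyms()]; tests and synthetic corpora use
#' [generate_fixture_lexicon()].
#'
#' @param mapping Named list; each element a character vector of synonyms
#'   for the name.
#' @return An object of class `synonym_lexicon`.
#' @export
synonym_lexicon <- function(mapping = list()) {
  stopifnot(is.list(mapping))
  if (length(mapping) > 0 && is.null(names(mapping))) {
    stop("`mapping` must be named by headword", call. = FALSE)
  }
  mapping <- lapply(stats::setNames(names(mapping), names(mapping)), function(w) {
    syns <- unique(as.character(mapping[[w]]))
    setdiff(syns, w)
  })
  mapping <- mapping[vapply(mapping, length, integer(1)) > 0]
  structure(list(mapping = mapping), class = "synonym_lexicon")
}

#' @export
print.synonym_lexicon <- function(x, ...) {
  cat("<synonym_lexicon> ", length(x$mapping), " headwords\n", sep = "")
  invisible(x)
}

#' Look up the synonyms of a word
#'
#' @param lexicon A `synonym_lexicon`.
#' @param word A single word.
#' @return Character vector of synonyms; empty for absent words.
#' @export
synonyms <- function(lexicon, word) {
  stopifnot(inherits(lexicon, "synonym_lexicon"))
  out <- lexicon$mapping[[word]]
  if (is.null(out)) character(0) else out
}

#' Load a synonym lexicon from a tab-separated file
#'
#' Expected dialect: one line per headword, `word<TAB>syn1,syn2,...`,
#' UTF-8, `#` comment lines ignored. Duplicate headword lines are merged
#' by set union; self-mappings are dropped. A malformed line (wrong field
#' count) raises an error naming the line number.
#'
#' @param path Path to the lexicon file.
#' @return A `synonym_lexicon`.
#' @export
load_synonyms <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  mapping <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2 || !nzchar(trimws(fields[1]))) {
      stop("malformed synonym line ", i, " in ", path, call. = FALSE)
    }
    word <- trimws(fields[1])
    syns <- trimws(strsplit(fields[2], ",", fixed = TRUE)[[1]])
    syns <- syns[nzchar(syns)]
    mapping[[word]] <- union(mapping[[word]], syns)
  }
  synonym_lexicon(mapping)
}

#' Write a synonym lexicon to the tab-separated dialect
#'
#' @param lexicon A `synonym_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_synonyms <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "synonym_lexicon"))
  words <- sort(names(lexicon$mapping))
  lines <- vapply(words, function(w) {
    paste0(w, "\t", paste(lexicon$mapping[[w]], collapse = ","))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a stopword list
#'
#' Stopwords are tokens protected from augmentation: synonym replacement
#' never replaces them and random insertion never uses them as a source.
#' Membership is exact string match; any case or width normalization is
#' the corpus's responsibility upstream.
#'
#' @param words Character vector of stopwords.
#' @param source_name Provenance string recorded on the list.
#' @return An object of class `stopword_list`.
#' @export
stopword_list <- function(words = character(), source_name = "unspecified") {
  structure(
    list(words = unique(as.character(words)), source_name = source_name),
    class = "stopword_list"
  )
}

#' @export
print.stopword_list <- function(x, ...) {
  cat("<stopword_list> ", length(x$words), " words (", x$source_name, ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.stopword_list <- function(x) length(x$words)

#' Load a stopword list from a file
#'
#' One word per line, UTF-8, `#` comment lines ignored. Entries in
#' `exclusions` are removed after loading: the intended use is to take a
#' general-purpose stopword list and strip the word classes that carry
#' clinical signal (e.g. demonstratives/pronouns, which speakers with
#' cognitive decline use at elevated rates and which must therefore stay
#' visible to augmentation-aware models).
#'
#' @param path Path to the stopword file.
#' @param exclusions Character vector of words to drop from the loaded
#'   list.
#' @param source_name Provenance string; defaults to the file name.
#' @return A `stopword_list`.
#' @export
load_stopwords <- function(path, exclusions = character(),
                           source_name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  words <- trimws(lines)
  words <- words[nzchar(words) & !startsWith(words, "#")]
  out <- setdiff(unique(words), exclusions)
  message("loaded ", length(out), " stopwords from ", basename(path))
  stopword_list(out, source_name)
}

#' Write a stopword list, one word per line
#'
#' @param stopwords A `stopword_list`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stopwords <- function(stopwords, path) {
  stopifnot(inherits(stopwords, "stopword_list"))
  writeLines(stopwords$words, path, useBytes = TRUE)
  invisible(path)
}

#' Test stopword membership
#'
#' @param word Character vector of tokens.
#' @param stopwords A `stopword_list`.
#' @return Logical vector, `TRUE` where the token is a stopword (exact
#'   match).
#' @export
is_stopword <- function(word, stopwords) {
  stopifnot(inherits(stopwords, "stopword_list"))
  word %in% stopwords$words
}
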