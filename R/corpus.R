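#' @keywords internal
"_PACKAGE"

# Placeholder substituted upstream for words that could not be deciphered.
ILLEGIBLE <- "xxx"

#' Tokenize a sentence
#'
#' Splits a sentence string into tokens. Word tokens are maximal alphabetic
#' runs; an apostrophe flanked by letters is kept inside the word, so
#' "didn't" is a single token. Digit runs and punctuation marks are returned
#' as non-word tokens so that character offsets remain recoverable.
#'
#' @param sentence_text A character string (one sentence, without its
#'   terminal period).
#' @return A data frame with one row per token and columns `surface`,
#'   `form` (lowercased surface), `start`/`end` (0-based, half-open character
#'   offsets into `sentence_text`), `is_word`, and `is_illegible` (`TRUE` for
#'   the `"xxx"` placeholder that stands for an unreadable word).
#' @examples
#' tokenize("The clinic was closed.")
#' tokenize("didn't")
#' @export
tokenize <- function(sentence_text) {
  stopifnot(is.character(sentence_text), length(sentence_text) == 1L)
  empty <- data.frame(
    surface = character(), form = character(),
    start = integer(), end = integer(),
    is_word = logical(), is_illegible = logical(),
    stringsAsFactors = FALSE
  )
  if (is.na(sentence_text) || !nzchar(sentence_text)) return(empty)
  pat <- "[[:alpha:]]+(?:'[[:alpha:]]+)*|[[:digit:]]+|[^[:space:]]"
  m <- gregexpr(pat, sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  surface <- substring(sentence_text, m, m + len - 1L)
  form <- tolower(surface)
  is_word <- grepl("^[[:alpha:]]", surface)
  data.frame(
    surface = surface, form = form,
    start = as.integer(m - 1L), end = as.integer(m - 1L + len),
    is_word = is_word,
    is_illegible = is_word & form == ILLEGIBLE,
    stringsAsFactors = FALSE
  )
}

#' Segment a text into sentences
#'
#' Narratives follow a normalized convention: every sentence starts with a
#' capital letter and ends with a period. Accordingly the text is split at
#' each period followed by whitespace or end of text; periods between digits
#' (decimal points) never split, and a trailing fragment with no final
#' period becomes the last sentence. Empty segments are dropped.
#'
#' @param text A character string with zero or more sentences.
#' @return A list of sentence objects, each a list with `index` (1-based
#'   ordinal), `text` (the sentence without its terminal period) and
#'   `tokens` (the [tokenize()] data frame).
#' @examples
#' length(segment_sentences("I went. It hurt."))
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(list())
  term <- gregexpr("\\.(?=[[:space:]]|$)", text, perl = TRUE)[[1]]
  if (term[1] == -1L) {
    pieces <- text
  } else {
    bounds <- as.integer(term)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds - 1L, nchar(text))
    pieces <- substring(text, starts, ends)
  }
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  out <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    out[[i]] <- list(index = i, text = pieces[i], tokens = tokenize(pieces[i]))
  }
  out
}

new_document <- function(id, raw) {
  doc <- list(id = id, raw = raw, sentences = segment_sentences(raw))
  class(doc) <- "nrx_document"
  doc
}

new_corpus <- function(documents) {
  ids <- vapply(documents, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate document ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  corpus <- list(documents = documents)
  class(corpus) <- "nrx_corpus"
  corpus
}

#' Build a corpus from in-memory texts
#'
#' @param texts Named character vector; names become document ids.
#' @return An object of class `nrx_corpus`.
#' @export
corpus_from_texts <- function(texts) {
  stopifnot(is.character(texts), length(texts) >= 1L)
  ids <- names(texts)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- sprintf("text_%03d", seq_along(texts))
  }
  new_corpus(mapply(new_document, ids, texts, SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

#' Load a corpus of narrative text files
#'
#' Reads every plain-text file in a directory (UTF-8, one narrative per
#' file), segments it into sentences and tokenizes it. Documents are ordered
#' deterministically by filename; ids are the filenames without extension.
#'
#' @param path Directory containing at least one readable text file.
#' @return An `nrx_corpus` object.
#' @export
load_corpus <- function(path) {
  if (!dir.exists(path)) stop("corpus directory does not exist: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- sort(files)
  if (length(files) == 0L) stop("no text files found in corpus directory: ", path)
  docs <- lapply(files, function(f) {
    raw <- readBin(f, what = "raw", n = file.size(f))
    txt <- rawToChar(raw)
    Encoding(txt) <- "UTF-8"
    if (!validUTF8(txt)) stop("file is not valid UTF-8: ", f)
    txt <- gsub("\r\n?", "\n", txt)
    txt <- gsub("\n+", " ", txt)
    new_document(tools::file_path_sans_ext(basename(f)), trimws(txt))
  })
  new_corpus(docs)
}

#' Write a corpus to a directory of text files
#'
#' @param corpus An `nrx_corpus`.
#' @param dir Output directory (created if needed). One `<id>.txt` per document.
#' @return Invisibly, the vector of file paths written.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "nrx_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(corpus$documents, function(doc) {
    p <- file.path(dir, paste0(doc$id, ".txt"))
    writeLines(doc$raw, p, useBytes = TRUE)
    p
  }, character(1))
  invisible(paths)
}

doc_word_forms <- function(doc) {
  unlist(lapply(doc$sentences, function(s) s$tokens$form[s$tokens$is_word]),
         use.names = FALSE)
}

#' Summary statistics for a text collection
#'
#' Counts, per text and in total, the sentences, word tokens (alphabetic
#' tokens including the illegibility placeholder) and distinct lowercased
#' wordform types. Means are total / number of texts, rounded to 2 decimals;
#' the type mean divides the corpus-level distinct-type total, so it is a
#' corpus-level rate rather than the average of per-text type counts.
#'
#' @param corpus A non-empty `nrx_corpus`.
#' @return An object of class `nrx_corpus_stats`.
#' @export
corpus_statistics <- function(corpus) {
  stopifnot(inherits(corpus, "nrx_corpus"))
  docs <- corpus$documents
  if (length(docs) == 0L) stop("corpus is empty")
  n <- length(docs)
  sent_per <- vapply(docs, function(d) length(d$sentences), integer(1))
  forms_per <- lapply(docs, doc_word_forms)
  tok_per <- vapply(forms_per, length, integer(1))
  typ_per <- vapply(forms_per, function(f) length(unique(f)), integer(1))
  total_types <- length(unique(unlist(forms_per, use.names = FALSE)))
  stats <- list(
    n_texts = n,
    sentences = list(total = sum(sent_per), mean = round(sum(sent_per) / n, 2),
                     min = min(sent_per), max = max(sent_per)),
    tokens = list(total = sum(tok_per), mean = round(sum(tok_per) / n, 2),
                  min = min(tok_per), max = max(tok_per)),
    types = list(total = total_types, mean = round(total_types / n, 2),
                 min_per_text = min(typ_per), max_per_text = max(typ_per))
  )
  class(stats) <- "nrx_corpus_stats"
  stats
}

#' @export
print.nrx_corpus_stats <- function(x, ...) {
  cat("Statistics for the text collection\n")
  fmt <- function(v) c("", format(v))
  tab <- data.frame(
    `Unit of analysis` = c("Texts", "Sentences", "Wordform tokens", "Wordform types"),
    `N (total)` = format(c(x$n_texts, x$sentences$total, x$tokens$total, x$types$total)),
    `Mean (in text)` = fmt(c(x$sentences$mean, x$tokens$mean, x$types$mean)),
    `Min (in text)` = fmt(c(x$sentences$min, x$tokens$min, x$types$min_per_text)),
    `Max (in text)` = fmt(c(x$sentences$max, x$tokens$max, x$types$max_per_text)),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.nrx_corpus <- function(x, ...) {
  cat(sprintf("<nrx_corpus: %d documents>\n", length(x$documents)))
  invisible(x)
}

#' @export
print.nrx_document <- function(x, ...) {
  cat(sprintf("<nrx_document '%s': %d sentences>\n", x$id, length(x$sentences)))
  invisible(x)
}

#' Write corpus statistics as a comma-separated table
#'
#' @param stats An `nrx_corpus_stats` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_corpus_stats <- function(stats, path) {
  stopifnot(inherits(stats, "nrx_corpus_stats"))
  tab <- data.frame(
    unit = c("texts", "sentences", "wordform_tokens", "wordform_types"),
    total = c(stats$n_texts, stats$sentences$total, stats$tokens$total, stats$types$total),
    mean = c(NA, stats$sentences$mean, stats$tokens$mean, stats$types$mean),
    min = c(NA, stats$sentences$min, stats$tokens$min, stats$types$min_per_text),
    max = c(NA, stats$sentences$max, stats$tokens$max, stats$types$max_per_text)
  )
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
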