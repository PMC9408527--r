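# Semantic-syntactic lexicon: named, non-exclusive groups of inflected
# wordforms, plus corpus frequency lists used to bootstrap them.

#' Frequency list of wordforms in a corpus
#'
#' One entry per distinct lowercased wordform, counting word-token
#' occurrences, sorted by descending count and then alphabetically.
#'
#' @param corpus A non-empty `nrx_corpus`.
#' @return A data frame of class `nrx_freq_list` with columns `form`, `count`.
#' @export
frequency_list <- function(corpus) {
  stopifnot(inherits(corpus, "nrx_corpus"))
  if (length(corpus$documents) == 0L) stop("corpus is empty")
  forms <- unlist(lapply(corpus$documents, doc_word_forms), use.names = FALSE)
  tab <- table(forms)
  out <- data.frame(form = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$form), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nrx_freq_list", "data.frame")
  out
}

#' Filter short wordforms out of a frequency list
#'
#' High-frequency closed-class function words (articles, prepositions,
#' pronouns) are mostly short; dropping forms below a minimum length is a
#' cheap surrogate for a stopword list when building a content-word lexicon.
#'
#' @param freq An `nrx_freq_list`.
#' @param min_len Minimum number of characters (of the lowercased form,
#'   apostrophes included) to retain. Default 4.
#' @return The filtered `nrx_freq_list`, order preserved.
#' @export
filter_short_words <- function(freq, min_len = 4L) {
  stopifnot(inherits(freq, "data.frame"), min_len >= 1L)
  out <- freq[nchar(freq$form) >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nrx_freq_list", "data.frame")
  out
}

#' Construct a word group
#'
#' @param name Unique group identifier.
#' @param members Character vector of wordforms (lowercased, trimmed,
#'   deduplicated on construction). Inflected forms are listed explicitly;
#'   no lemmatization is applied.
#' @param semantic Free-text semantic label.
#' @param syntactic Free-text syntactic label (e.g. "noun").
#' @return An object of class `nrx_word_group`.
#' @export
word_group <- function(name, members, semantic = "", syntactic = "") {
  members <- unique(trimws(tolower(members)))
  members <- members[nzchar(members)]
  if (length(members) == 0L) stop("word group '", name, "' has no members")
  g <- list(name = name, semantic = semantic, syntactic = syntactic,
            members = members)
  class(g) <- "nrx_word_group"
  g
}

#' Construct a lexicon from word groups
#'
#' Group membership is non-exclusive: the same wordform may belong to
#' several groups (e.g. a form used both as noun and adjective).
#'
#' @param groups List of `nrx_word_group` objects with unique names.
#' @return An object of class `nrx_lexicon`.
#' @export
lexicon <- function(groups) {
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(names(groups))) {
    stop("duplicate group names: ",
         paste(unique(names(groups)[duplicated(names(groups))]), collapse = ", "))
  }
  lex <- list(groups = groups)
  class(lex) <- "nrx_lexicon"
  lex
}

#' Load a lexicon from a directory of comma-separated group files
#'
#' Each `.csv` file defines one word group: comma-separated wordforms (line
#' breaks also separate entries), the filename minus extension as group name,
#' and an optional first-line header of the form
#' `#semantic=<label>,syntactic=<label>`.
#'
#' @param path Directory of group files.
#' @return An `nrx_lexicon`.
#' @export
load_lexicon <- function(path) {
  if (!dir.exists(path)) stop("lexicon directory does not exist: ", path)
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .csv group files in: ", path)
  groups <- lapply(files, function(f) {
    name <- tools::file_path_sans_ext(basename(f))
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    semantic <- ""; syntactic <- ""
    if (length(lines) > 0L && startsWith(lines[1], "#")) {
      hdr <- sub("^#", "", lines[1])
      fields <- strsplit(hdr, ",", fixed = TRUE)[[1]]
      for (fld in fields) {
        kv <- strsplit(fld, "=", fixed = TRUE)[[1]]
        if (length(kv) == 2L) {
          key <- trimws(kv[1]); val <- trimws(kv[2])
          if (key == "semantic") semantic <- val
          if (key == "syntactic") syntactic <- val
        }
      }
      lines <- lines[-1]
    }
    members <- unlist(strsplit(lines, ",", fixed = TRUE), use.names = FALSE)
    members <- trimws(members)
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("empty word-group file for group '", name, "': ", f)
    word_group(name, members, semantic = semantic, syntactic = syntactic)
  })
  lexicon(groups)
}

#' Groups containing a wordform
#'
#' Lookup is case-insensitive; the result may be empty, and may contain more
#' than one group since membership is non-exclusive.
#'
#' @param lex An `nrx_lexicon`.
#' @param form A wordform.
#' @return Character vector of group names.
#' @export
groups_of <- function(lex, form) {
  stopifnot(inherits(lex, "nrx_lexicon"))
  form <- tolower(form)
  hit <- vapply(lex$groups, function(g) form %in% g$members, logical(1))
  names(lex$groups)[hit]
}

#' Set relation between two word groups
#'
#' @param g1,g2 `nrx_word_group` objects.
#' @return One of `"equal"`, `"subordinate"` (g1 strictly contained in g2),
#'   `"superordinate"` (g1 strictly contains g2), `"independent"` (disjoint)
#'   or `"overlapping"`.
#' @export
group_relation <- function(g1, g2) {
  stopifnot(inherits(g1, "nrx_word_group"), inherits(g2, "nrx_word_group"))
  m1 <- g1$members; m2 <- g2$members
  common <- intersect(m1, m2)
  if (length(common) == 0L) return("independent")
  if (setequal(m1, m2)) return("equal")
  if (all(m1 %in% m2)) return("subordinate")
  if (all(m2 %in% m1)) return("superordinate")
  "overlapping"
}

#' @export
print.nrx_lexicon <- function(x, ...) {
  cat(sprintf("<nrx_lexicon: %d groups, %d distinct forms>\n",
              length(x$groups),
              length(unique(unlist(lapply(x$groups, `[[`, "members"))))))
  for (g in x$groups) {
    cat(sprintf("  %s [%s/%s]: %d members\n",
                g$name, g$semantic, g$syntactic, length(g$members)))
  }
  invisible(x)
}

#' Write a frequency list as a comma-separated file
#'
#' @param freq An `nrx_freq_list`.
#' @param path Output file (`form,count` per line).
#' @return Invisibly, `path`.
#' @export
write_frequency_list <- function(freq, path) {
  utils::write.csv(as.data.frame(freq), path, row.names = FALSE)
  invisible(path)
}
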