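# Lexical-syntactic frames: ordered sequences of constituents (quoted
# literal wordforms or G:<group> references) joined by binding operators:
#   ++  adjacent        constituents match immediately successive word tokens
#   +   within-sentence constituents match in order anywhere in one sentence
# Matching never crosses a sentence boundary.

OP_ADJACENT <- "adjacent"
OP_WITHIN <- "within"

#' Parse a lexical-syntactic frame expression
#'
#' Grammar: constituents alternate with binding operators, e.g.
#' `G:illness_noun + "hospital" ++ G:facility_noun`. Quoted tokens are
#' literal wordforms (lowercased); the `G:` prefix marks a word-group
#' reference. `++` binds adjacently, `+` within the sentence. Whitespace is
#' insignificant.
#'
#' @param expr Frame expression string.
#' @param id Frame identifier; defaults to the expression itself.
#' @return An object of class `nrx_frame` with `constituents` (list of
#'   `list(kind, value)` where kind is `"literal"` or `"group_ref"`) and
#'   `bindings` (character vector, one per consecutive pair).
#' @export
parse_frame <- function(expr, id = NULL) {
  stopifnot(is.character(expr), length(expr) == 1L)
  if (is.null(id)) id <- trimws(expr)
  n <- nchar(expr)
  i <- 1L
  items <- list() # each: list(type = "constituent"/"operator", ..., pos)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "\"") {
      close <- regexpr("\"", substring(expr, i + 1L), fixed = TRUE)
      if (close == -1L) stop("unterminated literal at position ", i, " in frame: ", expr)
      content <- substr(expr, i + 1L, i + close - 1L)
      if (!nzchar(trimws(content))) {
        stop("empty constituent at position ", i, " in frame: ", expr)
      }
      items[[length(items) + 1L]] <- list(
        type = "constituent",
        constituent = list(kind = "literal", value = tolower(trimws(content))),
        pos = i)
      i <- i + close + 1L
    } else if (substr(expr, i, i + 1L) == "G:") {
      m <- regexpr("^G:[A-Za-z0-9_.-]+", substring(expr, i))
      if (attr(m, "match.length") <= 2L) {
        stop("empty constituent at position ", i, " in frame: ", expr)
      }
      len <- attr(m, "match.length")
      name <- substr(expr, i + 2L, i + len - 1L)
      items[[length(items) + 1L]] <- list(
        type = "constituent",
        constituent = list(kind = "group_ref", value = name),
        pos = i)
      i <- i + len
    } else if (substr(expr, i, i + 1L) == "++") {
      items[[length(items) + 1L]] <- list(type = "operator", op = OP_ADJACENT, pos = i)
      i <- i + 2L
    } else if (ch == "+") {
      items[[length(items) + 1L]] <- list(type = "operator", op = OP_WITHIN, pos = i)
      i <- i + 1L
    } else {
      stop("unknown token at position ", i, " in frame: ", expr)
    }
  }
  if (length(items) == 0L) stop("empty frame expression")
  # validate alternation: constituent (operator constituent)*
  expect <- "constituent"
  for (it in items) {
    if (it$type != expect) {
      what <- if (it$type == "operator") "dangling operator" else "missing operator"
      stop(what, " at position ", it$pos, " in frame: ", expr)
    }
    expect <- if (expect == "constituent") "operator" else "constituent"
  }
  if (items[[length(items)]]$type == "operator") {
    stop("dangling operator at position ", items[[length(items)]]$pos,
         " in frame: ", expr)
  }
  constituents <- lapply(Filter(function(it) it$type == "constituent", items),
                         `[[`, "constituent")
  bindings <- vapply(Filter(function(it) it$type == "operator", items),
                     `[[`, character(1), "op")
  frame <- list(id = id, constituents = constituents, bindings = bindings)
  class(frame) <- "nrx_frame"
  frame
}

#' @export
print.nrx_frame <- function(x, ...) {
  parts <- vapply(x$constituents, function(co) {
    if (co$kind == "literal") paste0("\"", co$value, "\"") else paste0("G:", co$value)
  }, character(1))
  ops <- c(adjacent = "++", within = "+")[x$bindings]
  expr <- parts[1]
  for (k in seq_along(ops)) expr <- paste(expr, ops[k], parts[k + 1L])
  cat(sprintf("<nrx_frame %s> %s\n", x$id, expr))
  invisible(x)
}

#' Read frames from a file
#'
#' One frame expression per line; blank lines and lines starting with `#`
#' are ignored. Frame ids are `<basename>:<line>`.
#'
#' @param path Frame definition file.
#' @return List of `nrx_frame` objects.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("frame file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no frame expressions in: ", path)
  base <- basename(path)
  lapply(keep, function(ln) parse_frame(lines[ln], id = paste0(base, ":", ln)))
}

# Per-constituent candidate positions over the sentence's word-token
# subsequence. Illegible placeholders never match anything.
constituent_candidates <- function(constituent, forms, illegible, lex) {
  ok <- !illegible
  if (constituent$kind == "literal") {
    which(ok & forms == constituent$value)
  } else {
    g <- lex$groups[[constituent$value]]
    if (is.null(g)) stop("frame references unknown word group: ", constituent$value)
    which(ok & forms %in% g$members)
  }
}

#' Match a frame against one sentence
#'
#' Matching operates on the sentence's word tokens only, so punctuation and
#' digits are transparent: two word tokens separated by a comma still count
#' as adjacent. All matches are returned, ordered by position of the first
#' matched token.
#'
#' @param frame An `nrx_frame`.
#' @param sentence A sentence object (as produced by [segment_sentences()]).
#' @param lex An `nrx_lexicon` resolving every group reference.
#' @return A list of strictly increasing integer vectors, each giving the
#'   row indices in `sentence$tokens` matched by the frame's constituents.
#' @export
match_frame <- function(frame, sentence, lex) {
  stopifnot(inherits(frame, "nrx_frame"), inherits(lex, "nrx_lexicon"))
  toks <- sentence$tokens
  widx <- which(toks$is_word)
  k <- length(frame$constituents)
  if (length(widx) < k) return(list())
  forms <- toks$form[widx]
  illegible <- toks$is_illegible[widx]
  cand <- lapply(frame$constituents, constituent_candidates,
                 forms = forms, illegible = illegible, lex = lex)
  if (any(vapply(cand, length, integer(1)) == 0L)) return(list())
  results <- list()
  recurse <- function(ci, prefix) {
    prev <- prefix[length(prefix)]
    pool <- cand[[ci]]
    pool <- if (frame$bindings[ci - 1L] == OP_ADJACENT) {
      pool[pool == prev + 1L]
    } else {
      pool[pool > prev]
    }
    for (p in pool) {
      tup <- c(prefix, p)
      if (ci == k) {
        results[[length(results) + 1L]] <<- tup
      } else {
        recurse(ci + 1L, tup)
      }
    }
  }
  if (k == 1L) {
    results <- lapply(cand[[1L]], identity)
  } else {
    for (p in cand[[1L]]) recurse(2L, p)
    # DFS from sorted candidates emits tuples ordered by first position
  }
  lapply(results, function(tup) widx[tup])
}

#' Match a frame against every sentence of a document
#'
#' @param frame An `nrx_frame`.
#' @param doc An `nrx_document`.
#' @param lex An `nrx_lexicon`.
#' @return A data frame with one row per match: `doc_id`, `sentence`
#'   (index), `frame_id`, `positions` (list column of token indices) and
#'   `text` (the matched surface forms, space-joined).
#' @export
match_document <- function(frame, doc, lex) {
  stopifnot(inherits(doc, "nrx_document"))
  rows <- list()
  for (s in doc$sentences) {
    hits <- match_frame(frame, s, lex)
    for (h in hits) {
      rows[[length(rows) + 1L]] <- list(
        doc_id = doc$id, sentence = s$index, frame_id = frame$id,
        positions = h,
        text = paste(s$tokens$surface[h], collapse = " "))
    }
  }
  out <- data.frame(
    doc_id = vapply(rows, `[[`, character(1), "doc_id"),
    sentence = vapply(rows, `[[`, integer(1), "sentence"),
    frame_id = vapply(rows, `[[`, character(1), "frame_id"),
    text = vapply(rows, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
  out$positions <- lapply(rows, `[[`, "positions")
  out
}
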