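# Binary query classification: a query is a dichotomous question backed by a
# set of frames; a text scores 1 when at least one frame matches anywhere in
# it, else 0.

#' Construct a query
#'
#' @param id Query identifier (e.g. `"Q1"`).
#' @param question The natural-language dichotomous question.
#' @param frames Non-empty list of `nrx_frame` objects.
#' @return An object of class `nrx_query`.
#' @export
query <- function(id, question, frames) {
  if (inherits(frames, "nrx_frame")) frames <- list(frames)
  if (length(frames) == 0L) stop("query '", id, "' has no frames")
  stopifnot(all(vapply(frames, inherits, logical(1), "nrx_frame")))
  q <- list(id = id, question = question, frames = frames)
  class(q) <- "nrx_query"
  q
}

#' Read a query configuration file
#'
#' Comma-separated file with columns `id`, `frames` and `question`; `frames`
#' holds one or more frame-file paths (separated by `;`), resolved relative
#' to the configuration file's directory.
#'
#' @param path Configuration file path.
#' @return A named list of `nrx_query` objects, in file order.
#' @export
read_queries <- function(path) {
  if (!file.exists(path)) stop("query configuration does not exist: ", path)
  cfg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "frames", "question")
  if (!all(need %in% names(cfg))) {
    stop("query configuration must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  out <- lapply(seq_len(nrow(cfg)), function(i) {
    files <- trimws(strsplit(cfg$frames[i], ";", fixed = TRUE)[[1]])
    frames <- unlist(lapply(file.path(base, files), read_frames), recursive = FALSE)
    query(cfg$id[i], cfg$question[i], frames)
  })
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate query ids in: ", path)
  names(out) <- ids
  out
}

#' Classify one document against one query
#'
#' @param doc An `nrx_document`.
#' @param q An `nrx_query`.
#' @param lex An `nrx_lexicon`.
#' @return `1L` if any of the query's frames matches anywhere in the
#'   document, else `0L`.
#' @export
classify_document <- function(doc, q, lex) {
  stopifnot(inherits(q, "nrx_query"))
  for (fr in q$frames) {
    for (s in doc$sentences) {
      if (length(match_frame(fr, s, lex)) > 0L) return(1L)
    }
  }
  0L
}

#' Classify a corpus against a set of queries
#'
#' Produces the full document-by-query 0/1 score matrix along with an audit
#' trail: for every positive cell, the frame matches that support it, so a
#' human verifier can see why a text was classified positive.
#'
#' @param corpus An `nrx_corpus`.
#' @param queries Non-empty list of `nrx_query` objects.
#' @param lex An `nrx_lexicon`.
#' @return An object of class `nrx_classification` with elements `scores`
#'   (integer matrix, documents x queries), `audit` (nested list
#'   `audit[[doc_id]][[query_id]]`, a match data frame for positive cells)
#'   and `queries`.
#' @export
classify_corpus <- function(corpus, queries, lex) {
  stopifnot(inherits(corpus, "nrx_corpus"))
  if (length(queries) == 0L) stop("no queries supplied")
  stopifnot(all(vapply(queries, inherits, logical(1), "nrx_query")))
  qids <- unname(vapply(queries, `[[`, character(1), "id"))
  if (anyDuplicated(qids)) stop("duplicate query ids")
  dids <- unname(vapply(corpus$documents, `[[`, character(1), "id"))
  scores <- matrix(0L, nrow = length(dids), ncol = length(qids),
                   dimnames = list(dids, qids))
  audit <- stats::setNames(vector("list", length(dids)), dids)
  for (di in seq_along(corpus$documents)) {
    doc <- corpus$documents[[di]]
    cell_audit <- list()
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      hits <- do.call(rbind, lapply(q$frames, match_document, doc = doc, lex = lex))
      if (!is.null(hits) && nrow(hits) > 0L) {
        scores[di, qi] <- 1L
        cell_audit[[q$id]] <- hits
      }
    }
    audit[[di]] <- cell_audit
  }
  res <- list(scores = scores, audit = audit, queries = queries)
  class(res) <- "nrx_classification"
  res
}

# Round half away from zero (base round() rounds halves to even).
round_half_up <- function(x, digits = 1L) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Per-query positive counts and percentages
#'
#' @param object An `nrx_classification`.
#' @param n_texts Denominator for percentages; defaults to the number of
#'   classified documents.
#' @param ... Unused.
#' @return A data frame of class `nrx_query_summary` with columns `query`,
#'   `count` and `percent` (one decimal, half-up).
#' @export
summary.nrx_classification <- function(object, n_texts = nrow(object$scores), ...) {
  stopifnot(n_texts >= 1L)
  counts <- colSums(object$scores)
  out <- data.frame(
    query = colnames(object$scores),
    count = as.integer(counts),
    percent = round_half_up(100 * counts / n_texts, 1L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("nrx_query_summary", "data.frame")
  out
}

#' @rdname summary.nrx_classification
#' @param result An `nrx_classification`.
#' @export
summarize_classification <- function(result, n_texts = nrow(result$scores)) {
  summary(result, n_texts = n_texts)
}

#' @export
print.nrx_classification <- function(x, ...) {
  cat(sprintf("<nrx_classification: %d documents x %d queries>\n",
              nrow(x$scores), ncol(x$scores)))
  print(summary(x))
  invisible(x)
}

#' Write a classification score matrix as a comma-separated file
#'
#' One row per document: `doc_id,<query ids...>` with 0/1 cells.
#'
#' @param result An `nrx_classification`.
#' @param path Output file path.
#' @param audit_path Optional path for an audit file listing, for every
#'   positive cell, the matched frame and text span.
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path, audit_path = NULL) {
  stopifnot(inherits(result, "nrx_classification"))
  tab <- data.frame(doc_id = rownames(result$scores), result$scores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(audit_path)) {
    rows <- list()
    for (did in names(result$audit)) {
      for (qid in names(result$audit[[did]])) {
        h <- result$audit[[did]][[qid]]
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = did, query = qid, sentence = h$sentence,
          frame_id = h$frame_id, text = h$text, stringsAsFactors = FALSE)
      }
    }
    audit_tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(doc_id = character(), query = character(),
                 sentence = integer(), frame_id = character(),
                 text = character())
    utils::write.csv(audit_tab, audit_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a classification score matrix written by [write_results()]
#'
#' @param path CSV file with a `doc_id` column and 0/1 query columns.
#' @return Integer matrix, documents x queries.
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, setdiff(names(tab), "doc_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab$doc_id
  m
}
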