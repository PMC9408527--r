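# Benchmarking automatic classifications against two human readers:
# raw inter-rater agreement, 0/0.5/1 consensus ranks, Spearman rank
# correlation of automatic scores with the consensus, and a two-table report.

# Coerce yes/no, TRUE/FALSE or 0/1 answers to integer 0/1.
as_binary_answer <- function(x) {
  if (is.character(x)) {
    v <- tolower(trimws(x))
    bad <- !v %in% c("yes", "no")
    if (any(bad)) stop("invalid answer value(s): ", paste(unique(x[bad]), collapse = ", "))
    return(as.integer(v == "yes"))
  }
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (any(!x %in% c(0, 1))) stop("numeric answers must be 0 or 1")
    return(as.integer(x))
  }
  stop("unsupported answer type: ", class(x)[1])
}

#' Inter-rater agreement
#'
#' Raw (not chance-corrected) percentage of positions on which two readers
#' gave the same answer, reported to one decimal.
#'
#' @param r1,r2 Equal-length answer vectors (yes/no, logical, or 0/1).
#' @return Agreement in percent.
#' @export
interrater_agreement <- function(r1, r2) {
  a <- as_binary_answer(r1)
  b <- as_binary_answer(r2)
  if (length(a) != length(b)) stop("answer vectors differ in length")
  if (length(a) == 0L) stop("empty answer vectors")
  round_half_up(100 * mean(a == b), 1L)
}

#' Consensus rank of two readers' answers
#'
#' Per text: 1 when both readers answered yes, 0.5 when they split, 0 when
#' both answered no.
#'
#' @param r1,r2 Equal-length answer vectors (yes/no, logical, or 0/1).
#' @return Numeric vector in \{0, 0.5, 1\}.
#' @export
consensus_rank <- function(r1, r2) {
  a <- as_binary_answer(r1)
  b <- as_binary_answer(r2)
  if (length(a) != length(b)) stop("answer vectors differ in length")
  (a + b) / 2
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Spearman rank correlation with tie-aware p-value
#'
#' Both vectors are rank-transformed with midranks (average ranks over
#' ties — unavoidable here since the inputs take at most three distinct
#' values), then correlated with the product-moment formula. The two-sided
#' p-value uses the t approximation for n >= 10 and an exact permutation
#' distribution for n < 10. A constant input yields an explicitly flagged
#' undefined result rather than a silent NaN.
#'
#' @param auto Numeric vector (automatic 0/1 scores).
#' @param consensus Numeric vector of the same length (e.g. 0/0.5/1
#'   consensus ranks).
#' @return An object of class `nrx_spearman`: list with `rho`, `p_value`,
#'   `n`, `method` and `undefined`.
#' @export
spearman_rank <- function(auto, consensus) {
  x <- as.numeric(auto)
  y <- as.numeric(consensus)
  if (length(x) != length(y)) stop("vectors differ in length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  out <- list(rho = NA_real_, p_value = NA_real_, n = n,
              method = NA_character_, undefined = FALSE)
  class(out) <- "nrx_spearman"
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    out$undefined <- TRUE
    return(out)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  } else {
    perms <- all_perms(n)
    cx <- rx - mean(rx)
    cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    stat <- as.vector(matrix(cx[perms], nrow = nrow(perms)) %*% cy) / denom
    p <- mean(abs(stat) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  out$rho <- rho
  out$p_value <- min(p, 1)
  out$method <- method
  out
}

#' @export
print.nrx_spearman <- function(x, ...) {
  if (x$undefined) {
    cat("Spearman rank correlation: undefined (constant input)\n")
  } else {
    cat(sprintf("Spearman rho = %.3f, p = %.4g (%s, n = %d)\n",
                x$rho, x$p_value, x$method, x$n))
  }
  invisible(x)
}

#' Read human-reader responses
#'
#' Comma-separated file with columns `doc_id`, `reader_id` and one yes/no
#' column per query.
#'
#' @param path Responses file.
#' @return A named list, one data frame per reader (columns `doc_id` plus
#'   the query columns), ordered by reader id.
#' @export
read_reader_responses <- function(path) {
  if (!file.exists(path)) stop("reader responses file does not exist: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("doc_id", "reader_id") %in% names(tab))) {
    stop("reader responses need columns doc_id and reader_id")
  }
  readers <- split(tab[setdiff(names(tab), "reader_id")], tab$reader_id)
  lapply(readers, function(df) { rownames(df) <- NULL; df })
}

#' Write two readers' responses to one comma-separated file
#'
#' @param readers Named list of per-reader data frames (`doc_id` plus query
#'   columns of yes/no answers), as produced by [simulate_readers()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_reader_responses <- function(readers, path) {
  rows <- lapply(names(readers), function(rid) {
    df <- readers[[rid]]
    cbind(doc_id = df$doc_id, reader_id = rid,
          df[setdiff(names(df), "doc_id")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

reader_matrix <- function(reader, doc_ids, query_ids, label) {
  stopifnot(is.data.frame(reader), "doc_id" %in% names(reader))
  missing_docs <- setdiff(doc_ids, reader$doc_id)
  missing_q <- setdiff(query_ids, names(reader))
  if (length(missing_docs) || length(missing_q)) {
    stop("reader ", label, " is missing cells: ",
         paste(c(
           if (length(missing_docs)) paste("documents", paste(missing_docs, collapse = ", ")),
           if (length(missing_q)) paste("queries", paste(missing_q, collapse = ", "))
         ), collapse = "; "))
  }
  ord <- match(doc_ids, reader$doc_id)
  m <- sapply(query_ids, function(q) as_binary_answer(reader[[q]][ord]))
  m <- matrix(m, nrow = length(doc_ids), dimnames = list(doc_ids, query_ids))
  m
}

#' Build the evaluation report
#'
#' For every query: each reader's positive count and percentage, the
#' readers' mean, the automatic classifier's count and percentage, raw
#' inter-rater agreement, and the Spearman correlation between the automatic
#' 0/1 scores and the readers' 0/0.5/1 consensus ranks.
#'
#' @param results An `nrx_classification` (or its 0/1 score matrix with
#'   document-id rownames).
#' @param r1,r2 Per-reader data frames (`doc_id` plus yes/no query columns).
#' @param n_texts Percentage denominator; defaults to the number of
#'   classified documents.
#' @return A data frame of class `nrx_eval_report`.
#' @export
build_report <- function(results, r1, r2, n_texts = NULL) {
  scores <- if (inherits(results, "nrx_classification")) results$scores else results
  doc_ids <- rownames(scores)
  query_ids <- colnames(scores)
  if (is.null(n_texts)) n_texts <- length(doc_ids)
  m1 <- reader_matrix(r1, doc_ids, query_ids, "1")
  m2 <- reader_matrix(r2, doc_ids, query_ids, "2")
  rows <- lapply(query_ids, function(q) {
    c1 <- sum(m1[, q]); c2 <- sum(m2[, q])
    auto <- scores[, q]
    cons <- consensus_rank(m1[, q], m2[, q])
    sp <- spearman_rank(auto, cons)
    data.frame(
      query = q,
      reader1_count = c1, reader1_pct = round_half_up(100 * c1 / n_texts, 1L),
      reader2_count = c2, reader2_pct = round_half_up(100 * c2 / n_texts, 1L),
      readers_mean_count = (c1 + c2) / 2,
      readers_mean_pct = round_half_up(100 * ((c1 + c2) / 2) / n_texts, 1L),
      script_count = sum(auto),
      script_pct = round_half_up(100 * sum(auto) / n_texts, 1L),
      agreement_pct = interrater_agreement(m1[, q], m2[, q]),
      rho = if (sp$undefined) NA_real_ else round(sp$rho, 3L),
      p_value = sp$p_value,
      rho_undefined = sp$undefined,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_texts") <- n_texts
  class(out) <- c("nrx_eval_report", "data.frame")
  out
}

#' @export
print.nrx_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (n = %d texts)\n\n", attr(x, "n_texts")))
  cat("Classification counts and percentages:\n")
  print(as.data.frame(x)[, c("query", "reader1_count", "reader1_pct",
                             "reader2_count", "reader2_pct",
                             "readers_mean_count", "readers_mean_pct",
                             "script_count", "script_pct")],
        row.names = FALSE)
  cat("\nAgreement and rank correlation:\n")
  tab3 <- as.data.frame(x)[, c("query", "agreement_pct", "rho", "p_value")]
  tab3$rho <- ifelse(x$rho_undefined, "undefined", format(x$rho))
  print(tab3, row.names = FALSE)
  invisible(x)
}

#' Write the evaluation report as two comma-separated tables
#'
#' `table2.csv` holds the count/percentage columns; `table3.csv` the
#' agreement and correlation columns.
#'
#' @param report An `nrx_eval_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "nrx_eval_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t2 <- as.data.frame(report)[, c("query", "reader1_count", "reader1_pct",
                                  "reader2_count", "reader2_pct",
                                  "readers_mean_count", "readers_mean_pct",
                                  "script_count", "script_pct")]
  t3 <- as.data.frame(report)[, c("query", "agreement_pct", "rho", "p_value",
                                  "rho_undefined")]
  p2 <- file.path(dir, "table2.csv")
  p3 <- file.path(dir, "table3.csv")
  utils::write.csv(t2, p2, row.names = FALSE)
  utils::write.csv(t3, p3, row.names = FALSE)
  invisible(c(p2, p3))
}
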