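# Shared fixtures and independent oracles.

# First (or only) sentence of a text, as used by match_frame().
make_sentence <- function(text) {
  segment_sentences(text)[[1]]
}

# Small lexicon used across matching tests.
toy_lexicon <- function() {
  lexicon(list(
    word_group("illness_noun", c("fever", "pain", "injury", "flu")),
    word_group("facility_noun", c("hospital", "clinic", "pharmacy")),
    word_group("physician_noun", c("doctor", "doctors", "physician")),
    word_group("negative_verb", c("failed", "refused", "ignored"))
  ))
}

# Independent brute-force matching oracle: enumerate every strictly
# increasing tuple of word-token sequence positions and keep those whose
# tokens match the constituents and whose bindings are satisfied. Shares no
# code with match_frame()'s candidate-pruning DFS.
oracle_match <- function(frame, sentence, lex) {
  toks <- sentence$tokens
  widx <- which(toks$is_word)
  k <- length(frame$constituents)
  n <- length(widx)
  if (n < k) return(list())
  matches_constituent <- function(pos, co) {
    form <- toks$form[widx[pos]]
    if (toks$is_illegible[widx[pos]]) return(FALSE)
    if (co$kind == "literal") form == co$value
    else form %in% lex$groups[[co$value]]$members
  }
  tuples <- if (k == 1L) matrix(seq_len(n), ncol = 1L) else t(utils::combn(n, k))
  out <- list()
  for (r in seq_len(nrow(tuples))) {
    tup <- tuples[r, ]
    ok <- all(vapply(seq_len(k), function(ci) matches_constituent(tup[ci], frame$constituents[[ci]]),
                     logical(1)))
    if (ok && k > 1L) {
      for (b in seq_len(k - 1L)) {
        need_adj <- frame$bindings[b] == "adjacent"
        if (need_adj && tup[b + 1L] != tup[b] + 1L) { ok <- FALSE; break }
      }
    }
    if (ok) out[[length(out) + 1L]] <- widx[tup]
  }
  # order by position tuple, as match_frame documents
  if (length(out) > 1L) {
    key <- vapply(out, function(p) paste(sprintf("%04d", p), collapse = ""), character(1))
    out <- out[order(key)]
  }
  out
}

# Random sentence/frame pair over a small shared vocabulary, for the
# engine-vs-oracle equivalence property.
random_match_case <- function(lex) {
  vocab <- unique(c(unlist(lapply(lex$groups, `[[`, "members")),
                    "the", "a", "was", "and", "then", "very", "xxx"))
  n_words <- sample(1:15, 1)
  words <- sample(vocab, n_words, replace = TRUE)
  sentence <- make_sentence(paste0(paste(words, collapse = " "), "."))
  k <- sample(1:4, 1)
  constituents <- replicate(k, {
    if (stats::runif(1) < 0.5) {
      paste0("\"", sample(vocab, 1), "\"")
    } else {
      paste0("G:", sample(names(lex$groups), 1))
    }
  })
  ops <- sample(c("++", "+"), max(k - 1, 0), replace = TRUE)
  expr <- constituents[1]
  for (b in seq_along(ops)) expr <- paste(expr, ops[b], constituents[b + 1])
  list(frame = parse_frame(expr), sentence = sentence)
}

# Answer-vector helper for evaluation tests.
yn <- function(x) ifelse(x == 1, "yes", "no")

# All permutations of 1..n as a matrix, one per row (recursive insertion,
# written independently of the package internals).
gtools_style_perms <- function(n) {
  rows <- list(integer(0))
  for (v in seq_len(n)) {
    rows <- unlist(lapply(rows, function(r) {
      lapply(0:length(r), function(pos) append(r, v, after = pos))
    }), recursive = FALSE)
  }
  do.call(rbind, rows)
}
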