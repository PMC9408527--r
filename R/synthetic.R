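# Seeded synthetic patient-experience corpora with known ground truth.
# Documents are templated clinic-visit stories: neutral filler sentences plus,
# for each query a document is positive for, one planted sentence realized
# from that query's frames. Negative labels are guaranteed by screening every
# assembled document against the query frames and resampling on collision.

# Filler sentences deliberately avoid every wordform used by the example
# lexicon and frames; the screening step still backstops any future edit.
FILLER_POOL <- c(
  "I went there in the morning with my friend.",
  "We waited for about an hour in the hall.",
  "The building was big and quite old.",
  "My friend stayed with me the whole time.",
  "It was raining heavily that day.",
  "I had to fill in some forms at the desk.",
  "The waiting room was full of people.",
  "We took a taxi because it was far away.",
  "Everything was finished before noon.",
  "I went home and rested afterwards.",
  "The whole thing took around two hours.",
  "My roommate told me about this place.",
  "I was a student in my first year then.",
  "The appointment was early in the morning.",
  "I paid the fee at the counter.",
  "They gave me a paper with the details.",
  "The xxx was closed so we came back later.",
  "I remember the long corridor very well.",
  "It was my first month in the city.",
  "We found the address on the internet.",
  "The queue was long but it went fast.",
  "My brother called me in the evening.",
  "The weather was warm that week."
)

PLANT_PREFIXES <- c("I remember that", "That day", "During my time there",
                    "At one point", "Later on", "Honestly")
PLANT_SUFFIXES <- c("", "at the time", "back then", "for sure")
GAP_WORDS <- c("a", "the", "very", "quite", "really", "that", "some")

#' Synthetic-corpus generator configuration
#'
#' Defaults mirror the shape of the real study collection: 104 texts of 3-23
#' sentences, and per-query positive prevalences equal to the two human
#' readers' mean positive rates (Q1 0.394, Q2 0.808, Q3a 0.769, Q3b 0.577,
#' Q4 0.115).
#'
#' @param n_texts Number of documents to generate.
#' @param prevalence Named numeric vector in \[0, 1\]: probability that a
#'   document is positive for each query. Names must be query ids.
#' @param sentence_range Integer length-2 vector, inclusive bounds on
#'   sentences per document.
#' @param flip_prob Probability in \[0, 0.5) that a simulated reader flips a
#'   true label.
#' @param distractors If `TRUE`, some documents get a distractor: query
#'   vocabulary split across a sentence boundary, exercising the
#'   within-sentence constraint.
#' @param seed Integer random seed.
#' @return A list of class `nrx_generator_config`.
#' @export
generator_config <- function(n_texts = 104L,
                             prevalence = c(Q1 = 0.394, Q2 = 0.808,
                                            Q3a = 0.769, Q3b = 0.577,
                                            Q4 = 0.115),
                             sentence_range = c(3L, 23L),
                             flip_prob = 0,
                             distractors = TRUE,
                             seed = 1L) {
  stopifnot(n_texts >= 1L,
            all(prevalence >= 0), all(prevalence <= 1),
            length(sentence_range) == 2L,
            sentence_range[1] >= 1L, sentence_range[1] <= sentence_range[2],
            flip_prob >= 0, flip_prob < 0.5)
  if (is.null(names(prevalence)) || any(!nzchar(names(prevalence)))) {
    stop("prevalence must be a named vector of query ids")
  }
  cfg <- list(n_texts = as.integer(n_texts), prevalence = prevalence,
              sentence_range = as.integer(sentence_range),
              flip_prob = flip_prob, distractors = isTRUE(distractors),
              seed = as.integer(seed))
  class(cfg) <- "nrx_generator_config"
  cfg
}

# Realize a frame as a phrase: literals verbatim, group references by a
# sampled member; ++ joins directly, + inserts 1-2 neutral gap words.
realize_frame <- function(frame, lex) {
  words <- vapply(frame$constituents, function(co) {
    if (co$kind == "literal") return(co$value)
    g <- lex$groups[[co$value]]
    if (is.null(g)) stop("frame references unknown word group: ", co$value)
    sample(g$members, 1L)
  }, character(1))
  phrase <- words[1]
  for (k in seq_along(frame$bindings)) {
    sep <- if (frame$bindings[k] == OP_ADJACENT) {
      " "
    } else {
      paste0(" ", paste(sample(GAP_WORDS, sample(1:2, 1L)), collapse = " "), " ")
    }
    phrase <- paste0(phrase, sep, words[k + 1L])
  }
  phrase
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substring(x, 2L))
}

plant_sentence <- function(q, lex) {
  frame <- q$frames[[sample(length(q$frames), 1L)]]
  phrase <- realize_frame(frame, lex)
  suffix <- sample(PLANT_SUFFIXES, 1L)
  s <- paste(sample(PLANT_PREFIXES, 1L), phrase)
  if (nzchar(suffix)) s <- paste(s, suffix)
  paste0(capitalize(s), ".")
}

# Two sentences carrying a multi-constituent frame's vocabulary split across
# the boundary, so the frame itself must not match.
distractor_sentences <- function(queries, lex) {
  multi <- unlist(lapply(queries, function(q) {
    Filter(function(fr) length(fr$constituents) >= 2L, q$frames)
  }), recursive = FALSE)
  if (length(multi) == 0L) return(NULL)
  frame <- multi[[sample(length(multi), 1L)]]
  words <- vapply(frame$constituents, function(co) {
    if (co$kind == "literal") co$value else sample(lex$groups[[co$value]]$members, 1L)
  }, character(1))
  s1 <- paste0(capitalize(paste("Near the end it was all about", words[1])), ".")
  s2 <- paste0(capitalize(paste(paste(words[-1], collapse = " "),
                                "was on my mind afterwards")), ".")
  c(s1, s2)
}

assemble_document <- function(id, positives, queries, lex, cfg) {
  planted <- vapply(positives, function(qid) plant_sentence(queries[[qid]], lex),
                    character(1))
  extra <- NULL
  if (cfg$distractors && stats::runif(1) < 0.3) {
    extra <- distractor_sentences(queries, lex)
  }
  n_sent <- sample(cfg$sentence_range[1]:cfg$sentence_range[2], 1L)
  n_sent <- max(n_sent, length(planted) + length(extra))
  n_filler <- n_sent - length(planted) - length(extra)
  fillers <- sample(FILLER_POOL, n_filler, replace = TRUE)
  sentences <- fillers
  # keep distractor pair adjacent, then scatter planted sentences
  if (!is.null(extra)) {
    at <- sample(length(sentences) + 1L, 1L)
    sentences <- append(sentences, extra, after = at - 1L)
  }
  for (p in planted) {
    at <- sample(length(sentences) + 1L, 1L)
    sentences <- append(sentences, p, after = at - 1L)
  }
  new_document(id, paste(sentences, collapse = " "))
}

#' Generate a synthetic corpus with known ground truth
#'
#' Draws each document's true label per query from the configured
#' prevalence, plants a sentence realized from the query's frames for each
#' positive label, fills the rest with neutral clinic-visit sentences, and
#' screens every document so that intended-negative queries have no matching
#' phrase. Identical configuration (including seed) yields an identical
#' corpus.
#'
#' @param cfg An [generator_config()] object.
#' @param lex Lexicon resolving the queries' group references; defaults to
#'   the packaged example lexicon.
#' @param queries Named list of `nrx_query` objects; defaults to the
#'   packaged example queries. Every name in `cfg$prevalence` must identify
#'   one of them.
#' @return A list with `corpus` (`nrx_corpus`) and `truth` (integer matrix,
#'   documents x queries, the intended labels).
#' @export
generate_corpus <- function(cfg, lex = example_lexicon(),
                            queries = example_queries()) {
  stopifnot(inherits(cfg, "nrx_generator_config"))
  qids <- names(cfg$prevalence)
  unknown <- setdiff(qids, names(queries))
  if (length(unknown)) {
    stop("prevalence given for unknown or frame-less query: ",
         paste(unknown, collapse = ", "))
  }
  queries <- queries[qids]
  set.seed(cfg$seed)
  doc_ids <- sprintf("text_%04d", seq_len(cfg$n_texts))
  truth <- matrix(0L, nrow = cfg$n_texts, ncol = length(qids),
                  dimnames = list(doc_ids, qids))
  for (q in qids) {
    truth[, q] <- stats::rbinom(cfg$n_texts, 1L, cfg$prevalence[[q]])
  }
  docs <- vector("list", cfg$n_texts)
  for (i in seq_len(cfg$n_texts)) {
    positives <- qids[truth[i, ] == 1L]
    for (attempt in seq_len(100L)) {
      doc <- assemble_document(doc_ids[i], positives, queries, lex, cfg)
      got <- vapply(queries, function(q) classify_document(doc, q, lex),
                    integer(1))
      if (identical(unname(got), unname(truth[i, ]))) break
      doc <- NULL
    }
    if (is.null(doc)) {
      stop("could not realize ground truth for document ", doc_ids[i],
           " after 100 attempts; frames and fillers likely collide")
    }
    docs[[i]] <- doc
  }
  list(corpus = new_corpus(docs), truth = truth)
}

#' Simulate two independent human readers
#'
#' Each reader independently flips each true label with probability
#' `flip_prob`, emulating imperfect but unbiased readers.
#'
#' @param truth Integer 0/1 matrix (documents x queries) with dimnames.
#' @param flip_prob Flip probability in \[0, 0.5).
#' @param seed Integer random seed.
#' @return Named list of two data frames (`reader_1`, `reader_2`), each with
#'   `doc_id` and one yes/no column per query.
#' @export
simulate_readers <- function(truth, flip_prob, seed = 1L) {
  stopifnot(is.matrix(truth), flip_prob >= 0, flip_prob < 0.5)
  set.seed(as.integer(seed))
  one_reader <- function() {
    flips <- matrix(stats::rbinom(length(truth), 1L, flip_prob),
                    nrow = nrow(truth))
    ans <- abs(truth - flips)
    df <- data.frame(doc_id = rownames(truth), stringsAsFactors = FALSE)
    for (q in colnames(truth)) df[[q]] <- ifelse(ans[, q] == 1L, "yes", "no")
    df
  }
  list(reader_1 = one_reader(), reader_2 = one_reader())
}

#' Packaged example lexicon
#'
#' An illustrative reconstruction of a clinic-encounter lexicon (physician
#' and other-personnel nouns, communication nouns/verbs, illness nouns,
#' facility nouns, difficulty nouns, negation words, transfer verbs, and a
#' superordinate/subordinate event-noun pair). It is fixture data for the
#' shipped example queries, not a claim about any particular study's lexicon.
#'
#' @return An `nrx_lexicon`.
#' @export
example_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon", package = "narrex"))
}

#' Packaged example queries
#'
#' Five dichotomous patient-experience questions (language-communication
#' difficulty; illness/injury as visit reason; physician involvement;
#' non-physician personnel involvement; seeking help in more than one
#' facility), each backed by illustrative frames.
#'
#' @return Named list of `nrx_query` objects.
#' @export
example_queries <- function() {
  read_queries(system.file("extdata", "queries.csv", package = "narrex"))
}
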