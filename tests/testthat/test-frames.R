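test_that("frame expressions parse into constituents and bindings", {
  f1 <- parse_frame('"not" ++ "speak"')
  expect_length(f1$constituents, 2L)
  expect_equal(vapply(f1$constituents, `[[`, character(1), "kind"),
               c("literal", "literal"))
  expect_equal(f1$bindings, "adjacent")

  f2 <- parse_frame("G:physician_noun + G:negative_verb")
  expect_equal(vapply(f2$constituents, `[[`, character(1), "kind"),
               c("group_ref", "group_ref"))
  expect_equal(f2$bindings, "within")

  # whitespace-insensitive; literals lowercased
  f3 <- parse_frame('  "Language"++"Problem"  ')
  expect_equal(vapply(f3$constituents, `[[`, character(1), "value"),
               c("language", "problem"))
  expect_equal(f3$bindings, "adjacent")
})

test_that("malformed frame expressions fail with a position", {
  expect_error(parse_frame('"language" ++ + "problem"'), "position 15")
  expect_error(parse_frame('+ "problem"'), "dangling operator")
  expect_error(parse_frame('"problem" ++'), "dangling operator")
  expect_error(parse_frame('"" ++ "x"'), "empty constituent")
  expect_error(parse_frame('"a" "b"'), "missing operator")
  expect_error(parse_frame('"a" & "b"'), "unknown token")
  expect_error(parse_frame(""), "empty frame")
})

test_that("within-sentence binding allows gaps where adjacent does not", {
  lex <- toy_lexicon()
  sent <- make_sentence("The language was a big problem.")
  expect_length(match_frame(parse_frame('"language" + "problem"'), sent, lex), 1L)
  expect_length(match_frame(parse_frame('"language" ++ "problem"'), sent, lex), 0L)

  adj <- make_sentence("The language problem was big.")
  expect_length(match_frame(parse_frame('"language" ++ "problem"'), adj, lex), 1L)
})

test_that("matching never crosses a sentence boundary", {
  lex <- toy_lexicon()
  doc <- corpus_from_texts(c(d = "The doctor came. English was hard."))$documents[[1]]
  hits <- match_document(parse_frame('"doctor" + "english"'), doc, lex)
  expect_equal(nrow(hits), 0L)
})

test_that("group references match members, punctuation is transparent, illegible tokens never match", {
  lex <- toy_lexicon()
  s <- make_sentence("He had flu, then pain later.")
  hits <- match_frame(parse_frame("G:illness_noun + G:illness_noun"), s, lex)
  expect_length(hits, 1L)
  # an intervening comma does not break word-token adjacency
  s2 <- make_sentence("He had flu, pain and more.")
  expect_length(match_frame(parse_frame("G:illness_noun ++ G:illness_noun"), s2, lex), 1L)

  lex_x <- lexicon(list(word_group("g", c("xxx", "flu"))))
  s3 <- make_sentence("The xxx was flu.")
  hits3 <- match_frame(parse_frame("G:g"), s3, lex_x)
  expect_length(hits3, 1L) # only "flu"; the illegible placeholder never matches
  expect_length(match_frame(parse_frame('"xxx"'), s3, lex_x), 0L)

  expect_error(match_frame(parse_frame("G:no_such_group"), s, lex), "unknown word group")
})

test_that("all matches are returned in left-to-right order of first positions", {
  lex <- toy_lexicon()
  s <- make_sentence("Pain then pain then pain.")
  hits <- match_frame(parse_frame("G:illness_noun + G:illness_noun"), s, lex)
  expect_length(hits, 3L)
  firsts <- vapply(hits, `[[`, integer(1), 1L)
  expect_equal(firsts, sort(firsts))
})

test_that("match_document concatenates per-sentence matches with sentence indices", {
  lex <- toy_lexicon()
  doc <- corpus_from_texts(c(d = paste(
    "Nothing here. Still nothing. The doctor saw a doctor.",
    "No match again."
  )))$documents[[1]]
  hits <- match_document(parse_frame("G:physician_noun"), doc, lex)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$sentence, c(3L, 3L))
  expect_equal(hits$text, c("doctor", "doctor"))

  empty_doc <- corpus_from_texts(c(e = "Nothing relevant at all."))$documents[[1]]
  expect_equal(nrow(match_document(parse_frame("G:physician_noun"), empty_doc, lex)), 0L)
})

test_that("engine agrees with the brute-force enumeration oracle on randomized cases", {
  set.seed(2024)
  lex <- toy_lexicon()
  for (i in 1:400) {
    case <- random_match_case(lex)
    got <- match_frame(case$frame, case$sentence, lex)
    want <- oracle_match(case$frame, case$sentence, lex)
    expect_identical(got, want,
                     info = paste("frame:", case$frame$id,
                                  "sentence:", case$sentence$text))
  }
})

test_that("adding a group member never removes a match, and relaxing ++ to + keeps all matches", {
  set.seed(501)
  lex <- toy_lexicon()
  for (i in 1:60) {
    case <- random_match_case(lex)
    before <- match_frame(case$frame, case$sentence, lex)

    # enlarge every referenced group
    lex2 <- lex
    for (g in names(lex2$groups)) {
      lex2$groups[[g]]$members <- c(lex2$groups[[g]]$members, "zzznewword")
    }
    after <- match_frame(case$frame, case$sentence, lex2)
    expect_true(all(vapply(before, function(m) {
      any(vapply(after, identical, logical(1), m))
    }, logical(1))))

    # every adjacent match is a within-sentence match of the relaxed frame
    relaxed <- case$frame
    relaxed$bindings[] <- "within"
    rel <- match_frame(relaxed, case$sentence, lex)
    expect_true(all(vapply(before, function(m) {
      any(vapply(rel, identical, logical(1), m))
    }, logical(1))))
  }
})

test_that("inserting a period between matched tokens destroys the match", {
  set.seed(77)
  lex <- toy_lexicon()
  frame <- parse_frame("G:illness_noun + G:facility_noun")
  for (i in 1:40) {
    left <- sample(lex$groups$illness_noun$members, 1)
    right <- sample(lex$groups$facility_noun$members, 1)
    gap <- paste(sample(c("the", "was", "a", "big"), sample(0:3, 1), replace = TRUE),
                 collapse = " ")
    joined <- trimws(gsub("  +", " ", paste("He had", left, gap, right, "there.")))
    split_txt <- trimws(gsub("  +", " ",
                             paste0("He had ", left, ". ", "Then ", gap, " ", right, " there.")))
    doc1 <- corpus_from_texts(c(a = joined))$documents[[1]]
    doc2 <- corpus_from_texts(c(b = split_txt))$documents[[1]]
    expect_gt(nrow(match_document(frame, doc1, lex)), 0L)
    expect_equal(nrow(match_document(frame, doc2, lex)), 0L)
  }
})

test_that("frame files load line by line, skipping comments, with positional ids", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "q.txt")
  writeLines(c("# comment", "", '"not" ++ "speak"', "G:illness_noun"), p)
  frames <- read_frames(p)
  expect_length(frames, 2L)
  expect_equal(frames[[1]]$id, "q.txt:3")
  expect_error(read_frames(file.path(dir, "none.txt")), "does not exist")
  writeLines("# only a comment", p)
  expect_error(read_frames(p), "no frame expressions")
})
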