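---
title: "Rule-based querying of patient-experience narratives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based querying of patient-experience narratives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narrex)
```

## The problem

Free-text stories about healthcare encounters — short first- or third-person
accounts of a clinic or hospital visit — carry information about service
quality that closed-ended surveys miss: whether language was a barrier,
why the patient came, who treated them, whether they were bounced between
facilities. Reading hundreds of such stories by hand is expensive, and the
texts are too few, too topical and too idiosyncratic (second-language
English, simplified syntax, spelling quirks) for corpus-hungry statistical
classifiers to be a sensible first choice. `narrex` implements the classical
alternative: a small, hand-auditable rule system. Its components are

1. a **corpus layer** that reads one narrative per UTF-8 file, segments it
   into sentences and tokenizes it;
2. a **lexicon** of semantic–syntactic *word groups* — named sets of
   inflected wordforms sharing a meaning and usually a part of speech;
3. **lexical–syntactic frames** — ordered patterns over words and word
   groups with two binding operators — matched against each sentence;
4. a **classifier** that answers closed-ended dichotomous queries per text
   (score 1 if any of the query's frames matches anywhere, else 0);
5. an **evaluation protocol** benchmarking the automatic answers against
   two human readers;
6. a **synthetic-data generator** producing seeded corpora with known
   ground truth so the whole pipeline is testable without clinical data.

## Text conventions

The narratives the package targets are normalized upstream to one sentence
convention: a capital letter at the start, a period at the end. Accordingly
`segment_sentences()` splits **only** at a period followed by whitespace or
end of text. Exclamation and question marks do not split (the convention
normalizes them away), and a period between digits (a decimal point) never
splits. A trailing fragment without a final period is kept as a last
sentence. Words that were illegible in the source are represented by the
placeholder `xxx`; it is counted as a word token (it stands for a real
word) but can never match a frame constituent or lexicon entry (its
identity is unknown).

Tokens are maximal alphabetic runs; an apostrophe flanked by letters stays
inside the word, so `didn't` is one token. Digit runs and punctuation are
kept as non-word tokens with character offsets, but all counting and
matching operate on word tokens only. Every comparison uses lowercased
forms, so sentence-initial capitals cannot defeat lexicon lookup, and
"type" counts are counts of distinct lowercased forms.

One statistic needs a caveat: in the corpus summary the *mean types per
text* divides the corpus-level distinct-type total by the number of texts
(the convention used in this genre's descriptive tables). Because the
corpus-wide type inventory is shared across texts, that ratio is usually
far below any single text's own type count, so the summary also reports the
per-text minimum and maximum separately and the `min <= mean <= max`
relation is only meaningful for sentences and tokens.

## The lexicon

Lexicon construction starts from a frequency list (`frequency_list()`),
from which high-frequency closed-class function words are removed by a
minimum-length filter (`filter_short_words()`, default 4 characters of the
lowercased form, apostrophes included). Content words relevant to the
queries are then organized into word groups. Membership is deliberately
non-exclusive — one form may sit in several groups, as when a word serves
as both noun and adjective — and groups can stand in any set relation to
one another: `group_relation()` distinguishes independent, overlapping,
subordinate/superordinate and equal pairs (e.g. a group of negative event
nouns contained in a general event-noun group).

Groups live in plain comma-separated files (one file per group, filename =
group name, optional `#semantic=...,syntactic=...` header) so that a
domain expert can edit word lists without touching code. The package ships
an **illustrative example lexicon** for clinic-encounter stories
(physician nouns, other-personnel nouns, communication nouns and verbs,
illness nouns, facility nouns, difficulty nouns, negation words, transfer
verbs); it is fixture data demonstrating the format, not a validated
clinical resource.

## Frames and matching semantics

A frame is an ordered sequence of constituents joined by binding
operators:

```
G:communication_noun + G:difficulty_noun
"difficult" ++ "to" ++ G:communication_verb
```

Quoted tokens are literal wordforms; `G:` references a word group. `++`
(adjacent binding) requires the two constituents to match immediately
successive word tokens; `+` (within-sentence binding) requires them to
match in order within the same sentence, with any number of intervening
word tokens. A pattern is never searched across a sentence boundary.

Two matching decisions were genuinely open and are resolved as follows:

* **Punctuation is transparent.** Adjacency is defined over consecutive
  *word* tokens, so an intervening comma does not break `++`, and commas
  inside a sentence do not block `+`. Unedited narratives punctuate
  erratically; making adjacency punctuation-sensitive would turn matching
  into a punctuation test. The sentence-terminal period is the one hard
  boundary.
* **All matches are returned**, not just the first, even though
  classification only needs existence. The match set is the audit trail: a
  reviewer can see exactly which tokens supported a positive
  classification (`write_results(..., audit_path =)`).

Constituents carry no part-of-speech constraints; syntactic class is
realized extensionally through group membership. Matching is
case-insensitive throughout.

The engine enumerates matches by depth-first extension over per-constituent
candidate positions. Its correctness oracle in the test suite is a
brute-force enumerator over all strictly increasing position tuples,
checked for exact agreement on 1,100 randomized sentence/frame pairs
(sentences up to 15 word tokens, frames up to 4 constituents, fixed seed).

## Classification and summaries

A query pairs a dichotomous question with a non-empty frame set
(configured in a CSV mapping query id to frame files). A text scores 1 for
a query when at least one of its frames matches at least once, 0
otherwise. Summaries report positive counts and percentages of the corpus;
percentages are rounded half-up to one decimal, the convention of the
summary tables this output feeds.

## Evaluation against human readers

Two readers independently answer every query for every text. Three
statistics compare them with the classifier:

* **Inter-rater agreement**: the raw percentage of texts on which the two
  readers agree (no chance correction — the denominator is small and the
  statistic is meant to be read directly).
* **Consensus ranks**: per text, 1 if both readers said yes, 0.5 if they
  split, 0 if both said no — a three-level variable absorbing mild reader
  disagreement.
* **Spearman rank correlation** between the automatic 0/1 scores and the
  0/0.5/1 consensus. Both vectors are massively tied, so ranks use the
  midrank (average) method and rho is the product-moment correlation of
  the rank vectors; on tie-free data this reduces to the classical
  `1 - 6*sum(d^2)/(n*(n^2-1))` closed form, which the tests verify. The
  two-sided p-value uses the t approximation for n >= 10 and an exact
  permutation distribution below that. A constant vector (a query everyone
  answers the same way) makes rho undefined; the result is explicitly
  flagged rather than returned as NaN.

`build_report()` assembles counts, percentages, readers' means, agreement
and rho per query and serializes them as two CSV tables.

## The synthetic-data generator

`generate_corpus()` emulates the *shape* of a real narrative collection:
104 texts by default, 3–23 sentences each, with per-query positive
prevalences defaulting to the mean positive rates two human readers showed
on the five example queries (0.394, 0.808, 0.769, 0.577, 0.115). Each
document draws its true labels from those prevalences; for every positive
label one sentence is planted, realized from a randomly chosen frame of
that query (group references instantiated by sampled members, `+` bindings
padded with neutral gap words). The rest are filler sentences from a
neutral clinic-visit template pool chosen to avoid all query vocabulary,
and every assembled document is screened against every query's frames —
any accidental match on an intended-negative query triggers resampling —
so the ground-truth matrix is exact by construction. Optionally a
*distractor* is injected: a multi-constituent frame's vocabulary split
across a sentence boundary, which must not match and thereby exercises the
within-sentence constraint. `simulate_readers()` models two independent
readers who each flip every true label with a configurable probability
(default 0 in the generator; the acceptance script uses 0.04, for which
two independent readers agree on 92.3% of texts in expectation, the
mid-range of agreement levels typical of this task).

What the generator does **not** emulate — and therefore what green tests
do and do not show: templated filler gives far lower lexical diversity
than real narratives (the corpus-level type/text ratio comes out around 2
rather than ~14); there is no second-language grammar noise, no spelling
variation, no paraphrase outside the shipped frame inventory, and reader
errors are independent coin flips rather than systematic interpretation
differences. Passing the pipeline on synthetic data demonstrates that
segmentation, matching, classification and the evaluation arithmetic are
correct; it says nothing about the *recall* of any particular frame set on
real stories, which is exactly the part that requires domain work per
collection.

## Numerical and degenerate-input choices

* Percent rounding: half away from zero at one decimal (base `round()`
  half-to-even would give 0.15 -> 0.1).
* Means in corpus statistics: two decimals.
* rho reported to three decimals in reports; p-values unrounded.
* Empty corpus, empty directory, empty group file, empty query list,
  unresolved group reference, length-mismatched reader vectors: all are
  errors naming the offending object, never silent empties.
* Frames with a single constituent are legal (existence queries).
* `spearman_rank()` requires n >= 3 and flags constant input as undefined.

## Problem sizes used by the test suite

The suite favors many small randomized cases over few large ones: 1,100
randomized sentence/frame pairs for engine-vs-oracle equivalence, a
104-text synthetic corpus for exact end-to-end ground-truth recovery, a
500-text corpus for prevalence recovery against the 99% binomial bound,
1,000 simulated texts for the reader-agreement expectation, and
permutation-exact Spearman checks up to n = 8. These sizes keep each
property statistically meaningful while the whole suite stays fast.

## Limitations

The package matches surface wordforms only: no lemmatization, no
part-of-speech tagging, no negation scoping beyond what frames encode, no
regular-expression or bounded-gap constituents. A frame inventory is a
per-collection artifact — the shipped queries are illustrative
reconstructions, and applying the tool to a new population or language
variety means rebuilding the lexicon and frames from that collection's
frequency lists, which is the method's intended workflow rather than a
shortcut around it.
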