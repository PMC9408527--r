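# narrex

Rule-based information extraction from free-text patient-experience
narratives.

Health services collect short free-text stories about clinic and hospital
encounters — from patients, or from friends and relatives who accompanied
them. Questions like *"did language get in the way?"*, *"was the visit for
an illness or a checkup?"*, *"who besides a physician was involved?"*,
*"did the patient have to try more than one facility?"* can be answered
from such stories automatically, and for small, topically narrow,
stylistically homogeneous collections a transparent rule system does this
about as well as human readers, at a fraction of the cost and with a full
audit trail. `narrex` is that rule system, as an R package, for analysts
evaluating service quality from narrative collections.

## The method

1. **Corpus**: one narrative per UTF-8 file; sentences split only at a
   period followed by whitespace (the collections are normalized to that
   convention); word tokens are maximal alphabetic runs (`didn't` is one
   token); the placeholder `xxx` marks an illegible word — it counts as a
   token but never matches anything.
2. **Lexicon**: named *word groups* — sets of inflected wordforms of one
   semantic category and usually one part of speech, stored as editable
   comma-separated files. Membership is non-exclusive; groups may nest or
   overlap. Frequency lists with a minimum-length filter (default 4
   letters, which strips most closed-class function words) bootstrap the
   group inventory.
3. **Frames**: ordered patterns over literals and group references,

   ```
   G:communication_noun + G:difficulty_noun
   "difficult" ++ "to" ++ G:communication_verb
   ```

   where `++` binds *adjacent* word tokens and `+` binds *within the
   sentence* (any gap, never across a sentence boundary).
4. **Classifier**: a query = a dichotomous question + a frame set; a text
   scores **1** for a query iff at least one frame matches at least once,
   else **0**. Output is a document x query 0/1 matrix plus an audit of
   every supporting match.
5. **Evaluation**: two human readers answer the same questions; the
   package computes raw inter-rater agreement, 0/0.5/1 consensus ranks
   (both-yes / split / both-no) and the Spearman rank correlation (midrank
   ties, exact permutation p below n = 10, t approximation above) between
   the automatic scores and the consensus.
6. **Synthetic data**: a seeded generator plants frame-realizing sentences
   into neutral clinic-visit filler at configured prevalences, screens
   negatives for accidental matches, and simulates two imperfect readers —
   so the entire pipeline is testable with known ground truth.

## Worked example

```r
library(narrex)

lex     <- example_lexicon()   # illustrative clinic-encounter word groups
queries <- example_queries()   # five example queries Q1, Q2, Q3a, Q3b, Q4

# a 104-text synthetic collection with known ground truth
cfg <- generator_config(n_texts = 104, seed = 7)
gen <- generate_corpus(cfg, lex, queries)

corpus_statistics(gen$corpus)
#>  Unit of analysis N (total) Mean (in text) Min (in text) Max (in text)
#>             Texts       104
#>         Sentences      1383          13.30             3            23
#>   Wordform tokens      9899          95.18            15           170
#>    Wordform types       201           1.93            14            82

res <- classify_corpus(gen$corpus, queries, lex)
summary(res)
#>   query count percent
#> 1    Q1    39    37.5
#> 2    Q2    84    80.8
#> 3   Q3a    84    80.8
#> 4   Q3b    58    55.8
#> 5    Q4    13    12.5

identical(unname(res$scores), unname(gen$truth))
#> [1] TRUE
```

The score matrix equals the planted ground truth exactly: every planted
phrase is found and no filler text triggers a false positive. The counts
(39, 84, 84, 58, 13 of 104) are the binomial draws at the configured
prevalences. Benchmarking against two simulated readers who each misread
4% of labels:

```r
readers <- simulate_readers(gen$truth, flip_prob = 0.04, seed = 8)
build_report(res, readers$reader_1, readers$reader_2)
#>  query agreement_pct   rho      p_value
#>     Q1          93.3 0.964 2.107279e-60
#>     Q2          85.6 0.819 2.469510e-26
#>    Q3a          95.2 0.928 1.663515e-45
#>    Q3b          96.2 0.983 1.754541e-76
#>     Q4          93.3 0.848 8.094950e-30
```

Agreement sits around the ~92% a 4% flip rate implies, and the automatic
scores correlate strongly (rho 0.82–0.98, all p < 0.01) with the readers'
consensus — the pattern this kind of rule system shows when its frames fit
the collection. Matching semantics in one line:

```r
s <- segment_sentences("The language was a big problem.")[[1]]
match_frame(parse_frame("G:communication_noun + G:difficulty_noun"), s, lex)
#> [[1]]
#> [1] 2 6        # "language" ... "problem", any gap: match
match_frame(parse_frame("G:communication_noun ++ G:difficulty_noun"), s, lex)
#> list()         # adjacency required: no match
```

A thin command-line front-end wraps the same functions
(`inst/cli/narrex`): `stats`, `build-lexicon`, `classify`, `evaluate`,
`generate`.

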