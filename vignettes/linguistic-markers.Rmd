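---
title: "Linguistic markers of conspiracism: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linguistic markers of conspiracism: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

conspiratext scores dependency-parsed essays on linguistic markers that have
been linked to conspiracist ideation, joins those scores to rescaled
self-report trait measures, and provides the association statistics used in
individual-differences research. This vignette explains each metric, the
assumptions behind it, the tunable parameters, and the design decisions made
where more than one defensible choice existed.

## The data model

The pipeline does not tokenise, lemmatise or parse text itself. Its
canonical input is CoNLL-U, the ten-column format produced by any Universal
Dependencies toolchain (spaCy, stanza, UDPipe). This keeps the analysis core
deterministic and testable: a live parser is a preprocessing step outside
the package, and any parser that writes CoNLL-U can feed it. Internally a
`parsed_document` stores, per token, its 0-based position in the sentence,
surface form, lowercased lemma, UPOS tag and the 0-based index of its
syntactic head, with `NA` as the root sentinel; the reader converts
CoNLL-U's 1-based HEAD column at the boundary so a single convention holds
everywhere. Multiword-token ranges are skipped in favour of their syntactic
words; empty nodes are ignored; out-of-range heads are demoted to root with
a warning rather than an error, because a single bad parse should not sink a
corpus.

## Conspiratorial lexicon score

The dictionary method counts how many of a document's tokens match a
predefined list of conspiracy-associated lemmas and reports the proportion,
0 (no matches) to 1 (all words matched), so documents of different lengths
are comparable. Before matching, each text is reconstructed from its
lemmas: punctuation, symbols and numerals are removed by their UPOS tags
(PUNCT, SYM, NUM) — tag-driven filtering, since the input is already parsed
— except that `?` and `!` are retained as literal tokens, keyed on the
surface form, because conspiracy dictionaries can legitimately contain them.
Compounds are then joined (`sito web` becomes `sito_web`) by a greedy
left-to-right scan in which the longest matching rule wins and matches never
overlap; the rules are an explicit input file because no canonical rule list
exists.

Three choices here were genuinely open and are configurable:

* **Order of operations.** Filtering runs before compound joining by
  default (`join_first = FALSE` reverses it). Joining across an elided
  punctuation mark would create compounds that never appeared in the text.
* **Denominator.** The match ratio uses the post-joining token count,
  including retained `?`/`!`. A joined compound is one token and at most one
  match, keeping the ratio token-proportional; `count_punct = FALSE`
  excludes the punctuation channel entirely.
* **Empty documents** score `NA` with a warning rather than erroring, so a
  corpus run survives degenerate inputs and the missingness is visible
  downstream.

## Lexical sophistication and megalalia

Lexical sophistication maps an external norm table — ratings anchored in
age-of-acquisition judgments, where early-acquired words (*mamma*, *cibo*)
rate low and specialised terms (*sifilide*, *cherosene*) rate high — onto a
document's content lemmas and averages the mapped values (a token-pooled
mean over the whole document). Unmapped lemmas are skipped and the mapped
fraction is always reported as `coverage`, so low-coverage documents can be
filtered (no default threshold; the appropriate cutoff depends on the norm
set's vocabulary).

Megalalia — the disproportionate use of sophisticated vocabulary —
is the Gini coefficient of the within-document distribution of those same
ratings:

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar{x}}$$

A text whose words are uniformly simple (or uniformly sophisticated) scores
0; a text that drops a few highly sophisticated terms into otherwise plain
vocabulary scores high. The mean-absolute-difference form was fixed as the
package's definition because it is the most common one, scale-invariant and
bounded in $[0, 1 - 1/n]$; the implementation uses the algebraically
identical sorted-rank form ($O(n \log n)$) and the test suite verifies
agreement with the $O(n^2)$ pairwise sum to 1e-12. Gini requires
non-negative inputs, which is why norm tables must declare a non-negative
scale at load time, and at least two mapped values, so one-token documents
yield `NA` rather than a spurious 0.

## Syntactic sophistication

Three per-document metrics, each averaged over sentences:

1. **Mean sentence length** (tokens per sentence);
2. **Mean clauses per sentence**, proxied by the count of tokens tagged
   VERB or AUX — "all verbs including auxiliaries" is expressed in UD by
   those two tags;
3. **Mean maximal dependency distance**: per sentence, the maximum of
   $|i - \mathrm{head}(i)|$ over tokens, with the root contributing 0
   (a configurable `root_distance` exposes exclusion instead).

The composite is the first principal component of the three metrics,
computed on the correlation matrix (the metrics have different units, so
covariance PCA would let sentence length dominate). Eigenvectors are
sign-ambiguous, so the loading vector is oriented to make the
sentence-length loading positive; higher PC1 then always means more complex
syntax. `fit_syntactic_pca()` refuses zero-variance metrics by name, and
`score_pc1()` applies the stored standardisation so a model fitted on one
corpus can score another (`write_pca_model()`/`read_pca_model()` persist it
as plain text).

## Sequential cohesion

Cohesion is the mean cosine similarity between mean-word-vector embeddings
of adjacent sentences. Sentence vectors average the embeddings of tokens
that are not punctuation/symbols (by UPOS), not stopwords, and present in
the embedding vocabulary; the lookup keys on the lowercased surface form,
since embeddings are trained on running text (a `use_lemma` switch exists
for lemma-keyed vector sets). Out-of-vocabulary tokens are simply skipped —
no subword fallback, keeping the core dependency-free; any subword-capable
model can be exported to the same text vector format. When a sentence has
no embeddable token, the pairs it participates in are dropped (pair-level,
not document-level, deletion), and a document needs at least one usable
adjacent pair for a score, which is why cohesion can have a smaller n than
the other metrics in the same corpus.

The metric is validated by a scramble test: randomise sentence order
(preserving within-sentence word order; the permutation is guaranteed not
to be the identity), rescore, and compare arms. Documents with at least 20
sentences enter the validation, so that a scramble can meaningfully disrupt
order. The default comparison is an unpaired Welch t-test with pooled-SD
Cohen's d — the fractional degrees of freedom near $2n - 2$ that unpaired
comparison produces match how such validations are conventionally reported
— with a paired variant behind a flag. The packaged default stopword list
is a ~160-entry Italian function-word file under `inst/extdata/`; it is a
replaceable input, not a claim about the canonical Italian stopword
inventory.

## Trait scales

Likert responses are rescaled to a common 0–1 range by
$z = (x - \min L) / (\max L - \min L)$, so instruments with different
response ranges (an 11-item 1–7 scale, a 15-item 1–5 scale) become
comparable, with the midpoint of an odd scale at exactly .50. The composite
trait score is the mean of rescaled items. Two unspecified corners were
decided as: no items are reverse-keyed by default (declare them in
`scale_spec()` if the instrument has any), and missing items are handled by
an available-item mean with the missing count attached (strict mode yields
`NA` instead). Subscale scoring exists but item-to-subscale maps must be
supplied by the user.

## Association statistics

`pearson_ci()` reports r, a 95% Fisher-z interval and a t-distribution
p-value on pairwise-complete cases; `welch_t()` pairs the Welch statistic
and Satterthwaite df with pooled-SD Cohen's d; `correlation_matrix()`
assembles the usual lower-triangle report with stars at .05/.01/.001 and
per-cell n (pairwise deletion is deliberate: it reproduces the varying
degrees of freedom that arise when one metric — cohesion — is missing for a
few documents). No multiple-testing correction is applied by default,
matching exploratory reporting conventions; `adjust = "holm"` is available.
`moderated_regression()` z-standardises outcome, predictor and moderator,
forms the product *after* standardisation, and fits OLS, so the interaction
coefficient is the standardized moderation effect. Regressions use listwise
deletion, the matrix pairwise — the conventional split.

All of these are checked against direct-formula oracles written from the
textbook definitions (and against `stats::cor.test` where applicable) to
1e-10, and the Fisher-z interval is verified to achieve ~95% coverage over
2,000 simulated null datasets.

## The synthetic corpus generator

No essay corpus ships with the package, so every pipeline stage is
exercised on synthetic data with planted, recoverable structure. The
generator makes no claim to linguistic realism — lemmas are arbitrary
strings — it emulates the statistical structure the analysis assumes:

* **Trait-linked lexicon usage.** Each participant has a latent normal
  trait, squashed to 0–1; their Likert responses are generated from it and
  scored through the scales module, so the composite path is exercised
  end-to-end. The probability that a content token is drawn from the
  lexicon is a logistic function of the standardized trait. The intercept
  matches the configured base rate (default 0.10) and the slope is found by
  a one-dimensional root search on the analytically attenuation-corrected
  expected correlation — accounting for the binomial noise of the lexicon
  draws and the constant-rate `?`/`!` matches over the processed-token
  denominator — so the realized corpus correlation approaches the target
  (default .19, a weak effect typical of trait-language associations).
* **Megalalia.** A small probability of replacing a common word with a
  high-norm "sophisticated" word (default 0.04) rises with the trait;
  common-word norms are drawn from a low uniform band and spike words from
  a high one, so spikes raise the within-document Gini.
* **Topic-blocked cohesion.** Words live in topic clusters in embedding
  space (topic centroid plus isotropic noise); sentences share a topic in
  blocks of 5, and adjacent blocks differ. Adjacent sentences are therefore
  more similar than arbitrary pairs — exactly the signal the scramble test
  detects. With `n_topics = 1` the signal vanishes, which the tests use as
  a negative control.
* **Syntax.** Dependency trees attach each token either to its left
  neighbour or, with probability `p_long_head`, to the sentence root, so
  maximal dependency distance grows with sentence length and that
  probability. The complexity-contrast generator sets both high
  (long sentences, verb rate .35, long-head probability .6) and low arms
  from one shared vocabulary.

Defaults were chosen once to mirror the study conditions the pipeline
targets: 385 participants (one essay each), essays of 10–30 sentences of
6–14 tokens, verb rate .22, stopword rate .25, embedding dimension 50
(scaled down from the 300 dimensions of public fastText vectors — the
cohesion metric depends only on relative angles, not dimensionality), three
topics. The generator is fully deterministic under its mandatory seed, and
writing a corpus to disk and re-reading it reproduces the in-memory objects
byte-for-byte — the round-trip the test suite relies on.

What passing tests on this generator do **not** show: that the metrics
behave identically on real Italian essays, where lemmatisation errors,
out-of-vocabulary rates, topic drift within sentences and genuinely skewed
norm distributions are all messier than the generator's clean strata. The
synthetic results validate the *computations* and the *recoverability of
planted effects*, not the substantive psychology.

## Problem sizes and numerical choices

The shipped validation suite uses the sizes at which the planted effects
are statistically decisive yet cheap: 100 documents of ≥ 20 sentences for
the scramble test, 50 documents per arm for the complexity contrast, 500
and 1,000 participants for correlation recovery, and 200 replicates of
n = 1,000 for the moderation power check. All randomness flows through
explicit seeds; seeded helpers restore the caller's RNG state. Ties and
degenerate inputs are decided, not left to chance: empty processed
documents, unmappable documents and sub-2-sentence documents yield `NA`
(with warnings) rather than errors; zero-norm sentence vectors drop their
pairs; zero-variance inputs to PCA, correlations and regressions raise
errors naming the offending variable.

## Known limitations

* No subword embedding fallback; heavy OOV corpora will lose sentences.
* The clause proxy (VERB+AUX count) overcounts clauses in periphrastic
  tenses and undercounts verbless clauses; it is a deliberate, simple proxy.
* Megalalia inherits Gini's small-n volatility; very short documents should
  be filtered by `word_count` or `coverage` before interpretation.
* The moderated regressions assume linear, homoscedastic effects;
  standardized betas are descriptive, not causal.
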