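Package: conspiratext
Title: Individual-Level Linguistic Markers of Conspiracism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for scoring dependency-parsed essays on
    linguistic markers associated with conspiracist ideation: a
    dictionary-based conspiratorial-lexicon match ratio, lexical
    sophistication from age-of-acquisition-like norms, "megalalia" (the
    Gini coefficient of within-text sophistication ratings), syntactic
    sophistication (sentence length, clauses per sentence, maximum
    dependency distance, combined by PCA), and sequential semantic
    cohesion from word embeddings with a sentence-scrambling validation.
    Document scores are joined to rescaled Likert trait scores and
    analysed with Pearson correlations (Fisher-z intervals), Welch
    t-tests with Cohen's d, correlation matrices, and moderated
    regressions. A synthetic-corpus generator plants known effects so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
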