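# Fixture builders shared across test files. Everything is constructed in
# code; no binary fixtures.

# A parsed document from a compact spec: list of sentences, each a list of
# c(surface, lemma, upos, head0) rows (head0 = 0-based head or NA for root).
make_doc <- function(doc_id, sentences) {
  rows <- list()
  for (s in seq_along(sentences)) {
    sent <- sentences[[s]]
    for (i in seq_along(sent)) {
      tk <- sent[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        sentence = s, index = i - 1L, surface = tk[[1]], lemma = tk[[2]],
        upos = tk[[3]],
        head = if (is.na(tk[[4]])) NA_integer_ else as.integer(tk[[4]]),
        stringsAsFactors = FALSE)
    }
  }
  parsed_document(doc_id, do.call(rbind, rows))
}

# A single-sentence document from parallel lemma/upos vectors; heads form a
# left-branching chain with token 0 as root.
make_flat_doc <- function(lemmas, upos, doc_id = "doc", surfaces = lemmas) {
  n <- length(lemmas)
  parsed_document(doc_id, data.frame(
    sentence = 1L, index = seq_len(n) - 1L, surface = surfaces,
    lemma = lemmas, upos = upos,
    head = c(NA_integer_, seq_len(n - 1L) - 1L),
    stringsAsFactors = FALSE))
}

# A document whose content lemmas are given per sentence; all NOUN tokens.
make_noun_doc <- function(doc_id, sentence_lemmas) {
  make_doc(doc_id, lapply(sentence_lemmas, function(ls) {
    lapply(seq_along(ls), function(i) {
      list(ls[[i]], ls[[i]], "NOUN", if (i == 1) NA else i - 2L)
    })
  }))
}

# A small embedding table from a named list of numeric vectors.
make_emb <- function(vectors) {
  embedding_table(do.call(rbind, vectors) |>
                    (\(m) { rownames(m) <- names(vectors); m })())
}

# O(n^2) pairwise-sum Gini oracle (independent of the package's sorted form).
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}
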