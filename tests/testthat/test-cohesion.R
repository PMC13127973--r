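vec_file <- function(lines) {
  f <- tempfile(fileext = ".vec")
  writeLines(lines, f)
  f
}

test_that("embedding loader honours the declared dimension and dedups", {
  f <- vec_file(c("2 3", "casa 1 0 0", "mondo 0 1 0"))
  emb <- load_embeddings(f)
  expect_equal(emb$dim, 3L)
  expect_equal(nrow(emb$vectors), 2L)
  expect_equal(unname(emb$vectors["casa", ]), c(1, 0, 0))

  bad <- vec_file(c("1 3", "casa 1 0"))
  expect_error(load_embeddings(bad), "line 2")

  dup <- vec_file(c("3 2", "casa 1 0", "casa 9 9", "mondo 0 1"))
  expect_warning(e2 <- load_embeddings(dup), "duplicate")
  expect_equal(nrow(e2$vectors), 2L)
  expect_equal(unname(e2$vectors["casa", ]), c(1, 0))
})

test_that("embedding tables round-trip through the text vector format", {
  corpus <- generate_corpus(synthetic_config(n_participants = 3, seed = 5))
  f <- tempfile(fileext = ".vec")
  write_embeddings(corpus$embeddings, f)
  back <- load_embeddings(f)
  expect_equal(back$dim, corpus$embeddings$dim)
  expect_equal(back$vectors, corpus$embeddings$vectors, tolerance = 1e-6)
})

test_that("sentence vectors are stopword/punct-filtered means over the vocabulary", {
  emb <- make_emb(list(casa = c(1, 0), mondo = c(0, 1), vero = c(1, 1)))
  doc <- make_doc("d", list(
    list(list("la", "la", "DET", 1), list("Casa", "casa", "NOUN", NA)),
    list(list("il", "il", "DET", 1), list("punto", "punto", "NOUN", NA),
         list(".", ".", "PUNCT", 1)),
    list(list("casa", "casa", "NOUN", NA),
         list("mondo", "mondo", "NOUN", 0))))
  sents <- doc_sentences(doc)
  sw <- c("la", "il")
  # one in-vocabulary content word -> its vector (surface lowercased)
  expect_equal(sentence_vector(sents[[1]], emb, sw), c(1, 0))
  # nothing embeddable -> NULL
  expect_null(sentence_vector(sents[[2]], emb, sw))
  # two words -> midpoint
  expect_equal(sentence_vector(sents[[3]], emb, sw), c(0.5, 0.5))
})

test_that("sequential cohesion averages adjacent cosines and drops missing sides", {
  emb <- make_emb(list(a = c(1, 0), b = c(0, 1), ab = c(1, 1)))
  # identical sentences -> cosine 1
  doc1 <- make_noun_doc("d1", list(c("a", "a"), c("a", "a")))
  expect_equal(sequential_cohesion(doc1, emb)$value, 1)
  # orthogonal adjacent vectors -> 0
  doc2 <- make_noun_doc("d2", list("a", "b"))
  expect_equal(sequential_cohesion(doc2, emb)$value, 0)
  # cosines 1 and 0 -> mean 0.5
  doc3 <- make_noun_doc("d3", list("a", "a", "b"))
  cs3 <- sequential_cohesion(doc3, emb)
  expect_equal(cs3$value, 0.5)
  expect_equal(cs3$n_pairs, 2L)
  # middle sentence out of vocabulary: both its pairs are dropped
  doc4 <- make_noun_doc("d4", list("a", "zzz", "b"))
  cs4 <- sequential_cohesion(doc4, emb)
  expect_equal(cs4$n_pairs, 0L)
  expect_true(is.na(cs4$value))
  expect_equal(cs4$n_sentences_embedded, 2L)
  # single embeddable sentence -> missing value
  expect_true(is.na(sequential_cohesion(make_noun_doc("d5", list("a")),
                                        emb)$value))
})

test_that("cohesion is invariant to within-sentence token order", {
  emb <- make_emb(list(a = c(1, 0), b = c(0, 1), c = c(1, 1)))
  doc <- make_noun_doc("d", list(c("a", "b", "c"), c("b", "a")))
  rev_doc <- make_noun_doc("d", list(c("c", "b", "a"), c("a", "b")))
  expect_equal(sequential_cohesion(rev_doc, emb)$value,
               sequential_cohesion(doc, emb)$value)
})

test_that("scrambling permutes sentences deterministically and never no-ops", {
  corpus <- generate_corpus(synthetic_config(n_participants = 3, seed = 44))
  doc <- corpus$docs[[1]]
  s1 <- scramble_sentences(doc, seed = 10)
  s2 <- scramble_sentences(doc, seed = 10)
  expect_equal(s1$tokens, s2$tokens)
  expect_equal(nrow(s1$tokens), nrow(doc$tokens))
  expect_false(identical(s1$tokens$lemma, doc$tokens$lemma))
  expect_equal(sort(s1$tokens$lemma), sort(doc$tokens$lemma))

  two <- make_noun_doc("t", list(c("a", "b"), c("c", "d")))
  sw <- scramble_sentences(two, seed = 1)
  expect_equal(sw$tokens$lemma, c("c", "d", "a", "b"))
  expect_error(scramble_sentences(make_noun_doc("one", list("a")), seed = 1),
               "at least 2")
})

test_that("scramble validation is null for single-cluster docs, positive for topic-blocked", {
  # all sentences share one embedding cluster: order carries no signal
  cfg1 <- synthetic_config(n_participants = 40, n_topics = 1,
                           sentences_per_doc = c(20, 25), seed = 61)
  c1 <- generate_corpus(cfg1)
  v1 <- scramble_validation(c1$docs, c1$embeddings, c1$stopwords,
                            min_sentences = 20, seed = 2)
  expect_lt(abs(v1$d), 0.4)

  # topic-blocked documents: original order is more cohesive
  cfg2 <- synthetic_config(n_participants = 40,
                           sentences_per_doc = c(20, 25), seed = 62)
  c2 <- generate_corpus(cfg2)
  v2 <- scramble_validation(c2$docs, c2$embeddings, c2$stopwords,
                            min_sentences = 20, seed = 2)
  expect_gt(v2$d, 0.5)
  expect_equal(v2$direction, "original > scrambled")
  expect_lt(v2$p, 0.001)
})

test_that("the scramble filter and determinism contracts hold", {
  cfg <- synthetic_config(n_participants = 12, sentences_per_doc = c(5, 25),
                          seed = 9)
  corpus <- generate_corpus(cfg)
  v <- scramble_validation(corpus$docs, corpus$embeddings, corpus$stopwords,
                           min_sentences = 20, seed = 4)
  n_eligible <- sum(vapply(corpus$docs,
                           function(d) n_sentences(d) >= 20, TRUE))
  expect_equal(v$n_docs, n_eligible)
  v2 <- scramble_validation(corpus$docs, corpus$embeddings, corpus$stopwords,
                            min_sentences = 20, seed = 4)
  expect_equal(v2$t, v$t)
  expect_equal(v2$per_doc, v$per_doc)
})
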