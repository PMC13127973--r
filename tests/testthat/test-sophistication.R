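norms_fixture <- function() {
  norm_table(c(mamma = 2, cibo = 2, sifilide = 8, pizza = 2, pasta = 2,
               cherosene = 9), 1, 10)
}

test_that("lexical sophistication averages mapped ratings and reports coverage", {
  norms <- norms_fixture()
  d1 <- make_flat_doc(c("mamma", "cibo"), c("NOUN", "NOUN"))
  expect_equal(lexical_sophistication(d1, norms)$lexical_mean, 2)

  d2 <- make_flat_doc(c("mamma", "sifilide"), c("NOUN", "NOUN"))
  expect_equal(lexical_sophistication(d2, norms)$lexical_mean, 5)

  d3 <- make_flat_doc(c("mamma", "zzz"), c("NOUN", "NOUN"))
  ls3 <- lexical_sophistication(d3, norms)
  expect_equal(ls3$lexical_mean, 2)
  expect_equal(ls3$coverage, 0.5)

  # PUNCT/SYM/NUM are excluded before mapping
  d4 <- make_flat_doc(c("mamma", "?", "5"), c("NOUN", "PUNCT", "NUM"))
  expect_equal(lexical_sophistication(d4, norms)$coverage, 1)

  d5 <- make_flat_doc("zzz", "NOUN")
  expect_warning(ls5 <- lexical_sophistication(d5, norms), "undefined")
  expect_true(is.na(ls5$lexical_mean))
})

test_that("gini matches hand values, is scale invariant, and rejects bad input", {
  expect_equal(gini(c(3, 3, 3, 3)), 0)
  expect_equal(gini(c(1, 1, 1, 9)), 0.5)
  x <- c(0.3, 2.5, 1.1, 7.2, 0.4)
  expect_equal(gini(x * 17), gini(x))
  expect_error(gini(5), "at least 2")
  expect_error(gini(c(-1, 2)), "non-negative")
  expect_error(gini(c(0, 0)), "all-zero")
})

test_that("gini agrees with the O(n^2) pairwise oracle on random vectors", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    x <- runif(n, 0, 10)
    expect_equal(gini(x), gini_pairwise(x), tolerance = 1e-12)
    expect_lte(gini(x), 1 - 1 / n + 1e-12)
  }
})

test_that("megalalia is the gini of the mapped sophistication values", {
  norms <- norms_fixture()
  uniform <- make_flat_doc(c("pizza", "pasta", "cibo"), rep("NOUN", 3))
  expect_equal(megalalia(uniform, norms), 0)

  spiked <- make_flat_doc(c("pizza", "pasta", "pizza", "pasta", "pasta",
                            "cherosene"), rep("NOUN", 6))
  plain <- make_flat_doc(rep(c("pizza", "pasta"), 3), rep("NOUN", 6))
  expect_gt(megalalia(spiked, norms), megalalia(plain, norms))

  four <- norm_table(c(a = 1, b = 9), 0, 10)
  doc <- make_flat_doc(c("a", "a", "a", "b"), rep("NOUN", 4))
  expect_equal(megalalia(doc, four), gini_pairwise(c(1, 1, 1, 9)))
})

test_that("megalalia and lexical mean are sentence-order invariant and spike-monotone", {
  corpus <- generate_corpus(synthetic_config(n_participants = 4, seed = 8))
  for (doc in corpus$docs) {
    scr <- scramble_sentences(doc, seed = 3)
    expect_equal(megalalia(scr, corpus$norms), megalalia(doc, corpus$norms))
    expect_equal(lexical_sophistication(scr, corpus$norms)$lexical_mean,
                 lexical_sophistication(doc, corpus$norms)$lexical_mean)
  }
  # inserting one maximally sophisticated token raises both scores
  norms <- norm_table(c(a = 2, top = 10), 1, 10)
  base <- make_flat_doc(rep("a", 10), rep("NOUN", 10))
  spiked <- make_flat_doc(c(rep("a", 10), "top"), rep("NOUN", 11))
  expect_gt(megalalia(spiked, norms), 0)
  expect_gt(lexical_sophistication(spiked, norms)$lexical_mean,
            lexical_sophistication(base, norms)$lexical_mean)
})

test_that("syntactic metrics match hand-computed sentence statistics", {
  doc <- make_doc("d", list(
    list(list("io", "io", "PRON", 1), list("ho", "avere", "AUX", 2),
         list("visto", "vedere", "VERB", NA)),
    list(list("a", "a", "NOUN", NA), list("b", "b", "NOUN", 0),
         list("c", "c", "NOUN", 1), list("d", "d", "NOUN", 2),
         list("e", "e", "NOUN", 3))))
  sm <- syntactic_metrics(doc)
  expect_equal(sm$mean_sentence_length, 4)      # (3 + 5) / 2
  expect_equal(sm$mean_clauses, 1)              # (AUX+VERB=2, 0) / 2
  # sentence 1 distances: |0-1|, |1-2|, root 0 -> max 1; sentence 2: all 1
  expect_equal(sm$mean_max_dep_distance, 1)

  # heads (0->1, 1->ROOT, 2->1, 3->0): distances 1, 0, 1, 3 -> max 3
  doc2 <- make_doc("d2", list(list(
    list("a", "a", "NOUN", 1), list("b", "b", "VERB", NA),
    list("c", "c", "NOUN", 1), list("d", "d", "NOUN", 0))))
  expect_equal(syntactic_metrics(doc2)$mean_max_dep_distance, 3)
})

test_that("PCA composite standardises, orients, and reports explained variance", {
  set.seed(1)
  latent <- rnorm(200)
  collinear <- data.frame(mean_sentence_length = 10 + 2 * latent,
                          mean_clauses = 1 + 0.5 * latent,
                          mean_max_dep_distance = 3 + latent)
  m <- fit_syntactic_pca(collinear)
  expect_equal(m$explained_variance_ratio, 1)

  # one latent factor plus small noise: PC1 dominates
  noisy <- data.frame(
    mean_sentence_length = 10 + 2 * latent + rnorm(200, 0, 0.1 * 2),
    mean_clauses = 1 + 0.5 * latent + rnorm(200, 0, 0.1 * 0.5),
    mean_max_dep_distance = 3 + latent + rnorm(200, 0, 0.1))
  mn <- fit_syntactic_pca(noisy)
  expect_gt(mn$explained_variance_ratio, 0.8)

  # orientation: sentence-length loading positive, scores deterministic
  expect_gt(mn$loadings[1], 0)
  expect_equal(sqrt(sum(mn$loadings^2)), 1)
  s <- score_pc1(mn, noisy)
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_equal(var(s), mn$eigenvalue, tolerance = 1e-8)

  # anti-oriented data still yields a positively oriented first loading
  flipped <- noisy
  flipped$mean_sentence_length <- -flipped$mean_sentence_length
  expect_gt(fit_syntactic_pca(flipped)$loadings[1], 0)

  degenerate <- noisy
  degenerate$mean_clauses <- 1
  expect_error(fit_syntactic_pca(degenerate), "mean_clauses")
})

test_that("PC1 score variance equals the first eigenvalue on the fitting sample", {
  set.seed(7)
  lat <- rnorm(120)
  X <- data.frame(mean_sentence_length = 12 + 3 * lat + rnorm(120, 0, 1),
                  mean_clauses = 2 + lat + rnorm(120, 0, 0.5),
                  mean_max_dep_distance = 4 + lat + rnorm(120, 0, 0.8))
  m <- fit_syntactic_pca(X)
  s <- score_pc1(m, X)
  expect_equal(mean(s), 0, tolerance = 1e-10)
  # population-style eigenvalue vs sample variance of scores
  expect_equal(var(s), m$eigenvalue, tolerance = 1e-8)
})

test_that("a fitted PCA model survives a plain-text round trip", {
  set.seed(3)
  X <- data.frame(mean_sentence_length = rnorm(30, 10),
                  mean_clauses = rnorm(30, 2),
                  mean_max_dep_distance = rnorm(30, 3))
  m <- fit_syntactic_pca(X)
  p <- tempfile()
  write_pca_model(m, p)
  m2 <- read_pca_model(p)
  expect_equal(score_pc1(m2, X), score_pc1(m, X), tolerance = 1e-12)
  expect_equal(m2$explained_variance_ratio, m$explained_variance_ratio)
})
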