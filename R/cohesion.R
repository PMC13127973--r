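# Sequential semantic cohesion from word embeddings, with the
# sentence-scrambling validation harness.

#' Load word embeddings from text vector format
#'
#' Whitespace-delimited text vector format: a header line with the vocabulary
#' size and the dimension, then one line per token (`token v1 ... v_dim`).
#' Duplicate tokens keep their first occurrence with a warning.
#'
#' @param path Path to the `.vec` file.
#' @return An `embedding_table`: list with `dim` and `vectors` (a numeric
#'   matrix with one row per token, tokens as rownames).
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty embedding file: ", path)
  hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(hdr) != 2L) stop("embedding header must be '<count> <dim>'")
  dim <- as.integer(hdr[[2]])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  toks <- character(length(body))
  mat <- matrix(NA_real_, nrow = length(body), ncol = dim)
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(parts) != dim + 1L) {
      stop(sprintf("embedding line %d: expected %d components, got %d",
                   i + 1L, dim, length(parts) - 1L))
    }
    toks[[i]] <- tolower(parts[[1]])
    mat[i, ] <- as.numeric(parts[-1])
  }
  dup <- duplicated(toks)
  if (any(dup)) {
    warning(sprintf("%d duplicate token(s) in embedding file; first occurrence kept",
                    sum(dup)))
    mat <- mat[!dup, , drop = FALSE]
    toks <- toks[!dup]
  }
  rownames(mat) <- toks
  embedding_table(mat)
}

#' Construct an embedding table from a matrix
#' @param vectors Numeric matrix, one row per token; rownames are the tokens
#'   (lowercased).
#' @return An `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  rownames(vectors) <- tolower(rownames(vectors))
  if (anyDuplicated(rownames(vectors))) stop("duplicate tokens in embedding table")
  structure(list(dim = ncol(vectors), vectors = vectors),
            class = "embedding_table")
}

#' Write an embedding table in text vector format
#' @param emb An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  V <- emb$vectors
  writeLines(c(sprintf("%d %d", nrow(V), ncol(V)),
               vapply(seq_len(nrow(V)), function(i) {
                 paste(c(rownames(V)[i], sprintf("%.6f", V[i, ])),
                       collapse = " ")
               }, "")),
             con, useBytes = TRUE)
  invisible(path)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d tokens, dim %d>\n", nrow(x$vectors), x$dim))
  invisible(x)
}

#' Read a stopword list (one token per line)
#' @param path Path to the file; defaults to the packaged Italian
#'   function-word list.
#' @return Character vector of lowercased stopwords.
#' @export
read_stopwords <- function(path = system.file("extdata", "stopwords_it.txt",
                                              package = "conspiratext")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
}

cosine <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) return(NA_real_)
  sum(v * w) / (nv * nw)
}

#' Mean-word-vector representation of a sentence
#'
#' The sentence embedding is the mean of the word vectors of its tokens after
#' removing stopwords and punctuation/symbols; the lookup keys on the
#' lowercased surface form. Returns `NULL` when no token survives.
#'
#' @param sentence A sentence token data frame (one element of
#'   [doc_sentences()]).
#' @param emb An `embedding_table`.
#' @param stopwords Character vector of stopwords.
#' @param use_lemma Key the embedding lookup on lemmas instead of surfaces.
#' @return Numeric vector of length `emb$dim`, or `NULL`.
#' @export
sentence_vector <- function(sentence, emb, stopwords = character(0),
                            use_lemma = FALSE) {
  keys <- tolower(if (use_lemma) sentence$lemma else sentence$surface)
  keep <- !(sentence$upos %in% c("PUNCT", "SYM")) & !(keys %in% stopwords) &
    keys %in% rownames(emb$vectors)
  if (!any(keep)) return(NULL)
  v <- emb$vectors[keys[keep], , drop = FALSE]
  colMeans(v)
}

#' Sequential textual cohesion of a document
#'
#' Represents each sentence as its mean word vector and averages the cosine
#' similarity between embeddings of adjacent sentences. Pairs in which either
#' sentence has no embeddable token (or a zero-norm vector) are dropped; the
#' score is missing when fewer than one usable adjacent pair remains. Higher
#' values indicate more semantically continuous, structured discourse.
#'
#' @param doc A `parsed_document`.
#' @inheritParams sentence_vector
#' @return A `cohesion_score`: list with `doc_id`, `value` (mean adjacent
#'   cosine or `NA`), `n_pairs`, `n_sentences_embedded`.
#' @export
sequential_cohesion <- function(doc, emb, stopwords = character(0),
                                use_lemma = FALSE) {
  stopifnot(inherits(doc, "parsed_document"))
  sents <- doc_sentences(doc)
  vecs <- lapply(sents, sentence_vector, emb = emb, stopwords = stopwords,
                 use_lemma = use_lemma)
  embedded <- !vapply(vecs, is.null, TRUE)
  cosines <- numeric(0)
  if (length(vecs) >= 2L) {
    for (i in seq_len(length(vecs) - 1L)) {
      if (embedded[[i]] && embedded[[i + 1L]]) {
        cs <- cosine(vecs[[i]], vecs[[i + 1L]])
        if (is.na(cs)) {
          warning(sprintf("document '%s': zero-norm sentence vector; pair %d dropped",
                          doc$doc_id, i))
        } else {
          cosines <- c(cosines, cs)
        }
      }
    }
  }
  structure(list(doc_id = doc$doc_id,
                 value = if (length(cosines)) mean(cosines) else NA_real_,
                 n_pairs = length(cosines),
                 n_sentences_embedded = sum(embedded)),
            class = "cohesion_score")
}

#' @export
print.cohesion_score <- function(x, ...) {
  cat(sprintf("<cohesion_score '%s': %s over %d adjacent pairs>\n", x$doc_id,
              if (is.na(x$value)) "NA" else sprintf("%.4f", x$value),
              x$n_pairs))
  invisible(x)
}

#' Randomise sentence order, preserving word order within sentences
#'
#' Draws a uniform permutation of the sentences, re-drawing until it differs
#' from the identity (always possible for two or more sentences), so a
#' scrambled document is never accidentally the original. Deterministic under
#' `seed`.
#'
#' @param doc A `parsed_document` with >= 2 sentences.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A new `parsed_document` with permuted sentences.
#' @export
scramble_sentences <- function(doc, seed = NULL) {
  stopifnot(inherits(doc, "parsed_document"))
  sents <- doc_sentences(doc)
  k <- length(sents)
  if (k < 2L) stop("scramble_sentences requires at least 2 sentences")
  perm <- with_seed(seed, {
    p <- sample.int(k)
    while (identical(p, seq_len(k))) p <- sample.int(k)
    p
  })
  pieces <- sents[perm]
  for (i in seq_along(pieces)) pieces[[i]]$sentence <- i
  parsed_document(doc$doc_id, do.call(rbind, pieces))
}

#' Scramble-test validation of the cohesion metric
#'
#' Compares sequential cohesion of original documents against sentence-order
#' scrambled counterparts on documents with at least `min_sentences`
#' sentences. By default the two arms are compared with an unpaired Welch
#' t-test plus pooled-SD Cohen's d; a paired t-test is available. Scrambling
#' should lower cohesion whenever adjacent sentences are more semantically
#' similar than arbitrary sentence pairs.
#'
#' @param corpus List of `parsed_document`s.
#' @inheritParams sentence_vector
#' @param min_sentences Minimum sentence count for a document to enter the
#'   validation (default 20).
#' @param seed Optional integer seed controlling the scrambles.
#' @param paired Use a paired t-test instead of the unpaired Welch test.
#' @return A `scramble_validation`: `t`, `df`, `p`, `d`, `direction`,
#'   `n_docs` and a `per_doc` data frame of original/scrambled values.
#' @export
scramble_validation <- function(corpus, emb, stopwords = character(0),
                                min_sentences = 20L, seed = NULL,
                                paired = FALSE) {
  keep <- vapply(corpus, function(d) n_sentences(d) >= min_sentences, TRUE)
  corpus <- corpus[keep]
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                      length(corpus)))
  rows <- lapply(seq_along(corpus), function(i) {
    doc <- corpus[[i]]
    orig <- sequential_cohesion(doc, emb, stopwords)$value
    scr <- sequential_cohesion(scramble_sentences(doc, seed = seeds[[i]]),
                               emb, stopwords)$value
    data.frame(doc_id = doc$doc_id, original = orig, scrambled = scr,
               stringsAsFactors = FALSE)
  })
  per_doc <- do.call(rbind, rows)
  per_doc <- per_doc[stats::complete.cases(per_doc), , drop = FALSE]
  if (nrow(per_doc) < 2L) {
    stop("scramble_validation needs at least 2 usable documents per arm")
  }
  tt <- if (paired) {
    diff <- per_doc$original - per_doc$scrambled
    res <- stats::t.test(diff)
    list(t = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value, d = mean(diff) / stats::sd(diff))
  } else {
    w <- welch_t(per_doc$original, per_doc$scrambled)
    list(t = w$t, df = w$df, p = w$p, d = w$d)
  }
  structure(c(tt, list(
    direction = if (mean(per_doc$original) >= mean(per_doc$scrambled))
      "original > scrambled" else "original < scrambled",
    n_docs = nrow(per_doc), per_doc = per_doc, paired = paired)),
    class = "scramble_validation")
}

#' @export
print.scramble_validation <- function(x, ...) {
  cat(sprintf(
    "<scramble_validation: n = %d docs, %s; t(%.2f) = %.2f, p = %.3g, d = %.2f>\n",
    x$n_docs, x$direction, x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Write a scramble-validation report as delimited text
#' @param x A `scramble_validation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scramble_report <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# scramble validation: n_docs=%d paired=%s", x$n_docs,
                   x$paired),
           sprintf("# t=%.6f df=%.6f p=%.6g d=%.6f direction=%s",
                   x$t, x$df, x$p, x$d, x$direction))
  writeLines(hdr, con, useBytes = TRUE)
  utils::write.table(format(x$per_doc, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
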