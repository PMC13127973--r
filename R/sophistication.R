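# Lexical sophistication (norm mean), megalalia (Gini of within-text
# sophistication) and syntactic sophistication (three metrics + PCA composite).

#' Construct a sophistication norm table
#'
#' Maps lemmas to sophistication ratings on an age-of-acquisition-like scale:
#' early-acquired words score low, specialised vocabulary scores high. The
#' scale bounds are declared, not inferred from the data.
#'
#' @param ratings Named numeric vector: `lemma -> rating`. Names are
#'   lowercased and must be unique.
#' @param scale_min,scale_max Declared bounds of the rating scale.
#' @return An object of class `norm_table`.
#' @export
norm_table <- function(ratings, scale_min, scale_max) {
  stopifnot(is.numeric(ratings), !is.null(names(ratings)),
            scale_min < scale_max)
  names(ratings) <- tolower(names(ratings))
  if (anyDuplicated(names(ratings))) stop("duplicate lemmas in norm table")
  if (any(ratings < scale_min | ratings > scale_max)) {
    stop("ratings outside declared scale bounds [", scale_min, ", ",
         scale_max, "]")
  }
  if (scale_min < 0) {
    stop("norm scale must be non-negative (required by the Gini-based megalalia score)")
  }
  structure(list(ratings = ratings, scale_min = scale_min,
                 scale_max = scale_max), class = "norm_table")
}

#' Read a norm table from a delimited text file
#'
#' Format: a first comment line `# scale_min=<a> scale_max=<b>` declaring the
#' rating bounds, then a TAB-separated table with header columns `lemma` and
#' `rating`.
#'
#' @param path Path to the file.
#' @return A `norm_table`.
#' @export
read_norm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  m <- regmatches(first, regexec(
    "^#\\s*scale_min\\s*=\\s*([0-9.eE+-]+)\\s+scale_max\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) != 3L) {
    stop("norm table must start with '# scale_min=<a> scale_max=<b>': ", path)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("lemma", "rating") %in% names(df))) {
    stop("norm table needs columns 'lemma' and 'rating'")
  }
  norm_table(stats::setNames(df$rating, df$lemma),
             as.numeric(m[[2]]), as.numeric(m[[3]]))
}

#' Write a norm table
#' @param norms A `norm_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norm_table <- function(norms, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# scale_min=%g scale_max=%g", norms$scale_min,
                       norms$scale_max),
               "lemma\trating",
               sprintf("%s\t%.6f", names(norms$ratings), norms$ratings)),
             con, useBytes = TRUE)
  invisible(path)
}

#' @export
print.norm_table <- function(x, ...) {
  cat(sprintf("<norm_table: %d lemmas on [%g, %g]>\n", length(x$ratings),
              x$scale_min, x$scale_max))
  invisible(x)
}

#' Per-document lexical sophistication
#'
#' Maps sophistication ratings onto the document's content lemmas (tokens
#' tagged PUNCT/SYM/NUM are excluded) and averages them. Lemmas absent from
#' the norm table are skipped; `coverage` reports the mapped fraction so that
#' low-coverage documents can be filtered downstream.
#'
#' @param doc A `parsed_document`.
#' @param norms A `norm_table`.
#' @return List with `lexical_mean` (NA when nothing maps), `values` (the
#'   mapped ratings, in token order), `mapped_count` and `coverage`.
#' @export
lexical_sophistication <- function(doc, norms) {
  stopifnot(inherits(doc, "parsed_document"), inherits(norms, "norm_table"))
  lem <- doc$tokens$lemma[!(doc$tokens$upos %in% c("PUNCT", "SYM", "NUM"))]
  vals <- norms$ratings[lem]
  vals <- unname(vals[!is.na(vals)])
  n_content <- length(lem)
  if (!length(vals)) {
    warning(sprintf("document '%s': no lemma mapped to a norm; lexical sophistication undefined",
                    doc$doc_id))
    return(list(lexical_mean = NA_real_, values = numeric(0),
                mapped_count = 0L,
                coverage = if (n_content) 0 else NA_real_))
  }
  list(lexical_mean = mean(vals), values = vals,
       mapped_count = length(vals), coverage = length(vals) / n_content)
}

#' Gini coefficient of a value distribution
#'
#' Mean-absolute-difference form: `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`,
#' bounded in `[0, 1 - 1/n]`; 0 means perfect uniformity. Computed via the
#' O(n log n) sorted-rank identity, which is algebraically equal to the
#' pairwise sum.
#'
#' @param values Numeric vector, length >= 2, non-negative, not all zero.
#' @return The Gini coefficient.
#' @export
gini <- function(values) {
  if (length(values) < 2L) stop("gini requires at least 2 values")
  if (anyNA(values)) stop("gini: values contain NA")
  if (any(values < 0)) stop("gini requires non-negative values")
  if (all(values == 0)) stop("gini undefined for all-zero values")
  n <- length(values)
  x <- sort(values)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Megalalia: disproportionate use of sophisticated vocabulary
#'
#' The Gini coefficient of the within-text distribution of lexical
#' sophistication ratings. Zero reflects complete uniformity of
#' sophistication across the text; values approaching one indicate that a
#' small subset of sophisticated words contrasts sharply with an otherwise
#' simple vocabulary.
#'
#' @param doc A `parsed_document`.
#' @param norms A `norm_table`.
#' @return The megalalia score.
#' @export
megalalia <- function(doc, norms) {
  vals <- lexical_sophistication(doc, norms)$values
  gini(vals)
}

#' Syntactic sophistication metrics of one document
#'
#' Three per-document metrics, each a mean over sentences: token count
#' (sentence length), count of tokens tagged VERB or AUX (a proxy for
#' clauses), and the maximum dependency distance `|i - head(i)|` over the
#' sentence's tokens, where the root token contributes 0.
#'
#' @param doc A `parsed_document`.
#' @param root_distance Value contributed by root tokens to the dependency
#'   distances (default 0; set `NA` to exclude roots from the maximum).
#' @return One-row data frame with columns `doc_id`, `mean_sentence_length`,
#'   `mean_clauses`, `mean_max_dep_distance`.
#' @export
syntactic_metrics <- function(doc, root_distance = 0) {
  stopifnot(inherits(doc, "parsed_document"))
  sents <- doc_sentences(doc)
  if (!length(sents)) stop("empty document")
  lens <- vapply(sents, nrow, 0L)
  clauses <- vapply(sents, function(s) sum(s$upos %in% c("VERB", "AUX")), 0L)
  maxdep <- vapply(sents, function(s) {
    d <- abs(s$index - s$head)
    d[is.na(s$head)] <- root_distance
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    max(d)
  }, 0)
  data.frame(doc_id = doc$doc_id,
             mean_sentence_length = mean(lens),
             mean_clauses = mean(clauses),
             mean_max_dep_distance = mean(maxdep, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

SYNTACTIC_FEATURES <- c("mean_sentence_length", "mean_clauses",
                        "mean_max_dep_distance")

#' Fit the PCA composite of syntactic sophistication
#'
#' Z-standardises the three syntactic metrics across documents
#' (correlation-matrix PCA, appropriate because the metrics have different
#' units) and extracts the first principal component as the composite
#' syntactic-sophistication measure. The loading vector is oriented so that
#' the loading on mean sentence length is positive, removing the eigenvector
#' sign ambiguity.
#'
#' @param metrics Data frame with the three metric columns (>= 3 rows).
#' @return An object of class `syntactic_pca`: feature means/SDs, unit-norm
#'   PC1 `loadings`, `explained_variance_ratio`, `orientation` and
#'   `eigenvalue`.
#' @export
fit_syntactic_pca <- function(metrics) {
  X <- as.matrix(metrics[, SYNTACTIC_FEATURES])
  if (nrow(X) < 3L) stop("PCA requires at least 3 documents")
  if (anyNA(X)) stop("PCA input contains missing values")
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    stop("zero-variance metric(s): ",
         paste(SYNTACTIC_FEATURES[zero], collapse = ", "))
  }
  mus <- colMeans(X)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  loadings <- eg$vectors[, 1]
  orientation <- if (loadings[[1]] >= 0) 1 else -1
  structure(list(feature_means = mus, feature_sds = sds,
                 loadings = loadings * orientation,
                 explained_variance_ratio = eg$values[[1]] / sum(eg$values),
                 eigenvalue = eg$values[[1]],
                 orientation = orientation),
            class = "syntactic_pca")
}

#' Project documents onto the fitted syntactic composite
#' @param model A `syntactic_pca` from [fit_syntactic_pca()].
#' @param metrics Data frame with the three metric columns.
#' @return Numeric vector of PC1 scores.
#' @export
score_pc1 <- function(model, metrics) {
  stopifnot(inherits(model, "syntactic_pca"))
  X <- as.matrix(metrics[, SYNTACTIC_FEATURES])
  Z <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_sds, "/")
  drop(Z %*% model$loadings)
}

#' @export
print.syntactic_pca <- function(x, ...) {
  cat(sprintf("<syntactic_pca: PC1 explains %.1f%% of variance; loadings %s>\n",
              100 * x$explained_variance_ratio,
              paste(sprintf("%.3f", x$loadings), collapse = ", ")))
  invisible(x)
}

#' Serialise / restore a fitted syntactic PCA model
#'
#' Plain-text key-value format, one `key=value` per line, so a model fitted
#' on one corpus can be reapplied to another.
#'
#' @param model A `syntactic_pca`.
#' @param path File path.
#' @return `path` invisibly / the restored model.
#' @export
write_pca_model <- function(model, path) {
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    paste0("features=", paste(SYNTACTIC_FEATURES, collapse = ",")),
    paste0("feature_means=", num(model$feature_means)),
    paste0("feature_sds=", num(model$feature_sds)),
    paste0("loadings=", num(model$loadings)),
    paste0("explained_variance_ratio=", num(model$explained_variance_ratio)),
    paste0("eigenvalue=", num(model$eigenvalue)),
    paste0("orientation=", num(model$orientation))
  ), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  num <- function(k) as.numeric(strsplit(vals[[k]], ",", fixed = TRUE)[[1]])
  structure(list(feature_means = stats::setNames(num("feature_means"), SYNTACTIC_FEATURES),
                 feature_sds = stats::setNames(num("feature_sds"), SYNTACTIC_FEATURES),
                 loadings = num("loadings"),
                 explained_variance_ratio = num("explained_variance_ratio"),
                 eigenvalue = num("eigenvalue"),
                 orientation = num("orientation")),
            class = "syntactic_pca")
}
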