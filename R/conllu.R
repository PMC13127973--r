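#' @importFrom stats complete.cases cor lm na.omit pt qnorm quantile rnorm
#'   runif sd setNames uniroot var plogis qlogis rbinom coef confint
#' @importFrom utils read.delim write.table head
NULL

# Universal Dependencies POS tag set; anything else falls back to UNKNOWN.
UD_UPOS <- c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN",
             "NUM", "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM",
             "VERB", "X")

#' Construct a parsed document
#'
#' A `parsed_document` holds the dependency-parsed token stream of one text:
#' a data frame with one row per syntactic word, carrying the sentence number,
#' the 0-based position of the token within its sentence, the surface form,
#' the (lowercased) lemma, the Universal POS tag, and the 0-based
#' sentence-internal index of the syntactic head (`NA` marks the root).
#'
#' @param doc_id Document identifier, unique within a corpus.
#' @param tokens Data frame with columns `sentence`, `index`, `surface`,
#'   `lemma`, `upos`, `head`.
#' @return An object of class `parsed_document`.
#' @export
parsed_document <- function(doc_id, tokens) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  req <- c("sentence", "index", "surface", "lemma", "upos", "head")
  if (!all(req %in% names(tokens))) {
    stop("tokens must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(tokens) == 0L) stop("parsed_document must contain at least one token")
  tokens$lemma <- tolower(tokens$lemma)
  bad_lemma <- nzchar(tokens$surface) & !nzchar(tokens$lemma)
  if (any(bad_lemma)) tokens$lemma[bad_lemma] <- tolower(tokens$surface[bad_lemma])
  tokens$upos[!(tokens$upos %in% UD_UPOS)] <- "UNKNOWN"
  tokens <- tokens[req]
  rownames(tokens) <- NULL
  structure(list(doc_id = doc_id, tokens = tokens), class = "parsed_document")
}

#' @export
print.parsed_document <- function(x, ...) {
  cat(sprintf("<parsed_document '%s': %d sentences, %d tokens>\n",
              x$doc_id, n_sentences(x), nrow(x$tokens)))
  invisible(x)
}

#' Number of sentences in a parsed document
#' @param doc A `parsed_document`.
#' @return Integer sentence count.
#' @export
n_sentences <- function(doc) length(unique(doc$tokens$sentence))

#' Split a parsed document into per-sentence token data frames
#' @param doc A `parsed_document`.
#' @return List of data frames, in sentence order.
#' @export
doc_sentences <- function(doc) {
  split(doc$tokens, doc$tokens$sentence)
}

#' Read a CoNLL-U file into parsed documents
#'
#' Reads 10-column CoNLL-U. Document boundaries are taken from
#' `# newdoc id = <id>` comments; a file without any such comment becomes a
#' single document named after the file. Multiword-token ranges (`3-4`) are
#' skipped in favour of their syntactic words and empty nodes (`3.1`) are
#' ignored. The 1-based HEAD column is converted to the package's 0-based
#' sentence-internal convention, with HEAD `0` mapped to the root sentinel
#' (`NA`). Lemmas are lowercased at ingestion.
#'
#' @param path Path to a CoNLL-U file (UTF-8).
#' @param doc_id Identifier used when the file carries no `# newdoc id`
#'   comments; defaults to the file name without extension.
#' @return A list of `parsed_document` objects.
#' @export
read_conllu <- function(path, doc_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")

  docs <- list()
  cur_id <- NULL
  sent_rows <- list()       # rows of current sentence
  doc_rows <- list()        # completed sentence data frames of current doc
  sent_no <- 0L

  flush_sentence <- function() {
    if (!length(sent_rows)) return(invisible())
    sent_no <<- sent_no + 1L
    n <- length(sent_rows)
    df <- data.frame(
      sentence = rep(sent_no, n),
      index    = vapply(sent_rows, `[[`, 0L, "index"),
      surface  = vapply(sent_rows, `[[`, "", "surface"),
      lemma    = vapply(sent_rows, `[[`, "", "lemma"),
      upos     = vapply(sent_rows, `[[`, "", "upos"),
      head     = vapply(sent_rows, `[[`, NA_integer_, "head"),
      stringsAsFactors = FALSE
    )
    # head must be a valid in-sentence index and never the token itself
    bad <- !is.na(df$head) & (df$head >= n | df$head == df$index)
    if (any(bad)) {
      warning(sprintf("document '%s', sentence %d: %d head index(es) out of range; reassigned to root",
                      if (is.null(cur_id)) doc_id else cur_id, sent_no, sum(bad)))
      df$head[bad] <- NA_integer_
    }
    if (sum(is.na(df$head)) != 1L) {
      message(sprintf("document '%s', sentence %d: %d root-headed tokens (expected 1)",
                      if (is.null(cur_id)) doc_id else cur_id, sent_no, sum(is.na(df$head))))
    }
    doc_rows[[length(doc_rows) + 1L]] <<- df
    sent_rows <<- list()
  }
  flush_doc <- function() {
    flush_sentence()
    if (length(doc_rows)) {
      tokens <- do.call(rbind, doc_rows)
      docs[[length(docs) + 1L]] <<- parsed_document(
        if (is.null(cur_id)) doc_id else cur_id, tokens)
    }
    doc_rows <<- list()
    sent_no <<- 0L
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line)) { flush_sentence(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*newdoc id\\s*=\\s*(.+?)\\s*$", line))[[1]]
      if (length(m) == 2L) { flush_doc(); cur_id <- m[[2]] }
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L) {
      stop(sprintf("malformed CoNLL-U line %d: expected 10 tab-separated fields, got %d",
                   ln, length(fields)))
    }
    id <- fields[[1]]
    if (grepl("-", id, fixed = TRUE)) next   # multiword-token range
    if (grepl(".", id, fixed = TRUE)) next   # empty node
    idx <- suppressWarnings(as.integer(id))
    if (is.na(idx)) stop(sprintf("malformed CoNLL-U line %d: bad token ID '%s'", ln, id))
    head_raw <- fields[[7]]
    head0 <- if (head_raw %in% c("0", "_")) NA_integer_ else {
      h <- suppressWarnings(as.integer(head_raw))
      if (is.na(h)) stop(sprintf("malformed CoNLL-U line %d: bad HEAD '%s'", ln, head_raw))
      h - 1L
    }
    lemma <- fields[[3]]
    if (lemma == "_" || !nzchar(lemma)) lemma <- fields[[2]]
    sent_rows[[length(sent_rows) + 1L]] <- list(
      index = idx - 1L, surface = fields[[2]], lemma = tolower(lemma),
      upos = fields[[4]], head = head0)
  }
  flush_doc()
  if (!length(docs)) stop("no tokens found in ", path)
  docs
}

#' Write parsed documents to a CoNLL-U file
#'
#' Inverse of [read_conllu()]: emits `# newdoc id` and `# sent_id` comments
#' and 10-column token lines with 1-based IDs and HEAD (`0` for the root).
#'
#' @param docs A `parsed_document` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(docs, path) {
  if (inherits(docs, "parsed_document")) docs <- list(docs)
  con <- file(path, open = "wb")  # binary: byte-stable newlines across platforms
  on.exit(close(con))
  out <- character(0)
  for (doc in docs) {
    out <- c(out, sprintf("# newdoc id = %s", doc$doc_id))
    for (sent in doc_sentences(doc)) {
      out <- c(out, sprintf("# sent_id = %s-%d", doc$doc_id, sent$sentence[[1]]))
      head1 <- ifelse(is.na(sent$head), 0L, sent$head + 1L)
      deprel <- ifelse(is.na(sent$head), "root", "dep")
      out <- c(out, sprintf("%d\t%s\t%s\t%s\t_\t_\t%d\t%s\t_\t_",
                            sent$index + 1L, sent$surface, sent$lemma,
                            sent$upos, head1, deprel))
      out <- c(out, "")
    }
  }
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}
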