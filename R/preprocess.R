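# Lexicon-oriented preprocessing: lemmatized reconstruction, tag-driven
# filtering, compound joining.

#' Read a lexicon file
#'
#' One entry per line; `#` starts a comment; blank lines ignored. Entries are
#' single lemmas, underscore-joined multiword lemmas, or the literal
#' punctuation marks `?` and `!`. Entries are lowercased.
#'
#' @param path Path to the lexicon file.
#' @param name Lexicon name; defaults to the file name.
#' @return An object of class `lexicon` with fields `entries` and `name`.
#' @export
read_lexicon <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lexicon(lines[nzchar(lines)], name = name)
}

#' Construct a lexicon from a character vector
#' @param entries Character vector of entries (lowercased; no whitespace).
#' @param name Lexicon name.
#' @return A `lexicon` object.
#' @export
lexicon <- function(entries, name = "lexicon") {
  entries <- tolower(unique(entries))
  if (any(!nzchar(entries))) stop("lexicon entries must be non-empty")
  if (any(grepl("\\s", entries))) {
    stop("multiword lexicon entries must be underscore-joined, not contain whitespace")
  }
  structure(list(entries = entries, name = name), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s': %d entries>\n", x$name, length(x$entries)))
  invisible(x)
}

#' Read compound-joining rules
#'
#' One rule per line: a space-separated lemma sequence, a TAB, and the joined
#' entry it becomes (e.g. `sito web<TAB>sito_web`).
#'
#' @param path Path to the rule file.
#' @return A list of rules, each `list(pattern = <chr vector>, entry = <chr>)`.
#' @export
read_compound_rules <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed compound rule: ", line)
    compound_rule(strsplit(tolower(parts[[1]]), " +")[[1]], tolower(parts[[2]]))
  })
}

#' Construct a compound rule
#' @param pattern Character vector: the lemma sequence to match.
#' @param entry Single string the sequence is replaced by.
#' @return A rule usable by [preprocess_for_lexicon()].
#' @export
compound_rule <- function(pattern, entry) {
  stopifnot(length(pattern) >= 1L, length(entry) == 1L)
  list(pattern = tolower(pattern), entry = tolower(entry))
}

# Greedy left-to-right scan: at each position the longest matching rule wins;
# matches never overlap; reapplication is a no-op because joined entries
# contain underscores while patterns are plain lemma sequences.
apply_compound_rules <- function(tokens, rules) {
  if (!length(rules) || !length(tokens)) return(tokens)
  rules <- rules[order(-vapply(rules, function(r) length(r$pattern), 0L))]
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- FALSE
    for (r in rules) {
      k <- length(r$pattern)
      if (i + k - 1L <= n && identical(tokens[i:(i + k - 1L)], r$pattern)) {
        out <- c(out, r$entry)
        i <- i + k
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      out <- c(out, tokens[[i]])
      i <- i + 1L
    }
  }
  out
}

#' Reconstruct a document as processed lemma tokens for dictionary scoring
#'
#' Concatenates the document's lowercased lemmas in order, drops tokens tagged
#' PUNCT, SYM or NUM — except those whose surface form is `?` or `!`, which
#' are retained as the literal tokens `"?"`/`"!"` because they can themselves
#' be dictionary entries — and then joins compounds by a greedy left-to-right
#' scan of `compound_rules` (longest rule first, non-overlapping).
#'
#' @param doc A `parsed_document`.
#' @param compound_rules List of rules from [read_compound_rules()] or
#'   [compound_rule()]; may be `NULL`.
#' @param join_first If `TRUE`, compounds are joined on the full lemma stream
#'   before punctuation/symbol/number removal instead of after (the default).
#' @return Character vector of processed tokens (possibly empty).
#' @export
preprocess_for_lexicon <- function(doc, compound_rules = NULL,
                                   join_first = FALSE) {
  stopifnot(inherits(doc, "parsed_document"))
  tok <- doc$tokens
  keep_punct <- tok$surface %in% c("?", "!")
  drop <- tok$upos %in% c("PUNCT", "SYM", "NUM") & !keep_punct
  toks <- ifelse(keep_punct, tok$surface, tok$lemma)
  if (!join_first) {
    return(apply_compound_rules(toks[!drop], compound_rules))
  }
  # join on the raw stream, then filter; a joined compound is always kept
  res <- scan_compounds_keep(toks, !drop, compound_rules)
  res
}

# Same greedy scan, but carries a per-token keep flag so filtering can be
# applied after joining without losing alignment.
scan_compounds_keep <- function(tokens, keep, rules) {
  if (!length(rules)) return(tokens[keep])
  rules <- rules[order(-vapply(rules, function(r) length(r$pattern), 0L))]
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- FALSE
    for (r in rules) {
      k <- length(r$pattern)
      if (i + k - 1L <= n && identical(tokens[i:(i + k - 1L)], r$pattern)) {
        out <- c(out, r$entry)
        i <- i + k
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      if (keep[[i]]) out <- c(out, tokens[[i]])
      i <- i + 1L
    }
  }
  out
}
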