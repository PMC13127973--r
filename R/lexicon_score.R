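# Dictionary-based conspiratorial-lexicon scoring.

#' Score a document against a conspiratorial lexicon
#'
#' Runs [preprocess_for_lexicon()] and counts the processed tokens whose
#' string is an entry of the dictionary. The score is the match ratio
#' `matches / denominator`, ranging from 0 (no dictionary matches) to 1
#' (every processed token matched). The denominator is the number of
#' processed tokens after compound joining, including retained `?`/`!`
#' tokens, which are themselves potential entries; each token contributes at
#' most one match, and a joined compound counts as one token.
#'
#' @param doc A `parsed_document`.
#' @param lexicon A `lexicon` object.
#' @param compound_rules Optional compound rules (see
#'   [preprocess_for_lexicon()]).
#' @param count_punct If `FALSE`, retained `?`/`!` tokens are excluded from
#'   the denominator (they still never match in that mode).
#' @return An object of class `lexicon_score`: list with `doc_id`, `matches`,
#'   `denominator`, `ratio` (`NA` when no processed tokens remain).
#' @export
score_lexicon <- function(doc, lexicon, compound_rules = NULL,
                          count_punct = TRUE) {
  stopifnot(inherits(doc, "parsed_document"), inherits(lexicon, "lexicon"))
  toks <- preprocess_for_lexicon(doc, compound_rules)
  if (!count_punct) toks <- toks[!(toks %in% c("?", "!"))]
  denom <- length(toks)
  if (denom == 0L) {
    warning(sprintf("document '%s': no processed tokens; lexicon ratio undefined",
                    doc$doc_id))
    return(structure(list(doc_id = doc$doc_id, matches = 0L,
                          denominator = 0L, ratio = NA_real_),
                     class = "lexicon_score"))
  }
  matches <- sum(toks %in% lexicon$entries)
  structure(list(doc_id = doc$doc_id, matches = matches,
                 denominator = denom, ratio = matches / denom),
            class = "lexicon_score")
}

#' @export
print.lexicon_score <- function(x, ...) {
  cat(sprintf("<lexicon_score '%s': %d/%d = %s>\n", x$doc_id, x$matches,
              x$denominator,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio)))
  invisible(x)
}
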