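# Config-driven end-to-end run: input directory -> per-document features
# joined to participant traits -> correlation matrix, moderation models,
# optional scramble validation, and a log.

#' Build a pipeline run configuration
#'
#' @param corpus Path to a CoNLL-U corpus file.
#' @param lexicon Path to the lexicon file.
#' @param norms Path to the norm table.
#' @param embeddings Path to the embedding `.vec` file (required when
#'   cohesion is computed).
#' @param stopwords Path to the stopword list (`NULL` for the packaged
#'   default).
#' @param participants Path to the participant table (TSV with header; must
#'   contain `doc_id` and `conspiracism`).
#' @param output_dir Directory for `features.tsv`, `correlations.tsv`,
#'   `moderation.tsv`, `scramble_report.tsv` and `run.log`.
#' @param compound_rules Optional path to a compound-rule file.
#' @param min_sentences Minimum sentences for the scramble validation.
#' @param coverage_threshold Minimum norm coverage for a document's lexical
#'   scores to be retained (`NULL` = no filter).
#' @param scramble If `TRUE`, run the scramble validation.
#' @param strict If `TRUE`, join failures abort the run instead of being
#'   logged and skipped.
#' @param seed Integer seed for the scrambles.
#' @return A `run_config` list (paths are checked at [run_pipeline()] time).
#' @export
run_config <- function(corpus, lexicon, norms, embeddings = NULL,
                       stopwords = NULL, participants, output_dir,
                       compound_rules = NULL, min_sentences = 20L,
                       coverage_threshold = NULL, scramble = TRUE,
                       strict = FALSE, seed = 1L) {
  structure(list(corpus = corpus, lexicon = lexicon, norms = norms,
                 embeddings = embeddings, stopwords = stopwords,
                 participants = participants, output_dir = output_dir,
                 compound_rules = compound_rules,
                 min_sentences = as.integer(min_sentences),
                 coverage_threshold = coverage_threshold,
                 scramble = isTRUE(scramble), strict = isTRUE(strict),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments; relative paths are resolved against the file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) NULL
    else if (grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(base, p)
  }
  for (k in c("corpus", "lexicon", "norms", "embeddings", "stopwords",
              "participants", "output_dir", "compound_rules")) {
    if (!is.null(vals[[k]])) vals[[k]] <- rel(vals[[k]])
  }
  do.call(run_config, vals)
}

#' Compute the per-document feature table
#'
#' One row per document: token counts, lexicon match ratio, lexical
#' sophistication and coverage, megalalia, the three syntactic metrics with
#' their PCA composite, and sequential cohesion (when embeddings are given).
#'
#' @param docs List of `parsed_document`s.
#' @param lexicon A `lexicon`.
#' @param norms A `norm_table`.
#' @param embeddings Optional `embedding_table`.
#' @param stopwords Stopword character vector (used for cohesion).
#' @param compound_rules Optional compound rules.
#' @param coverage_threshold If set, lexical mean and megalalia of documents
#'   with lower norm coverage are masked to `NA`.
#' @return Data frame of document features; the fitted `syntactic_pca` is
#'   attached as attribute `"pca"`.
#' @export
compute_features <- function(docs, lexicon, norms, embeddings = NULL,
                             stopwords = character(0), compound_rules = NULL,
                             coverage_threshold = NULL) {
  rows <- lapply(docs, function(doc) {
    lx <- suppressWarnings(score_lexicon(doc, lexicon, compound_rules))
    ls <- suppressWarnings(lexical_sophistication(doc, norms))
    mg <- if (length(ls$values) >= 2L && !all(ls$values == 0))
      gini(ls$values) else NA_real_
    sm <- syntactic_metrics(doc)
    ch <- if (!is.null(embeddings))
      sequential_cohesion(doc, embeddings, stopwords)$value else NA_real_
    data.frame(doc_id = doc$doc_id,
               word_count = sum(!(doc$tokens$upos %in%
                                    c("PUNCT", "SYM", "NUM"))),
               n_sentences = n_sentences(doc),
               lexicon_ratio = lx$ratio,
               lexical_mean = ls$lexical_mean,
               coverage = ls$coverage,
               megalalia = mg,
               mean_sentence_length = sm$mean_sentence_length,
               mean_clauses = sm$mean_clauses,
               mean_max_dep_distance = sm$mean_max_dep_distance,
               cohesion = ch,
               stringsAsFactors = FALSE)
  })
  feats <- do.call(rbind, rows)
  if (!is.null(coverage_threshold)) {
    low <- !is.na(feats$coverage) & feats$coverage < coverage_threshold
    feats$lexical_mean[low] <- NA_real_
    feats$megalalia[low] <- NA_real_
  }
  pca <- NULL
  ok <- stats::complete.cases(feats[, SYNTACTIC_FEATURES])
  if (sum(ok) >= 3L) {
    pca <- tryCatch(fit_syntactic_pca(feats[ok, ]), error = function(e) NULL)
  }
  feats$pc1 <- NA_real_
  if (!is.null(pca)) feats$pc1[ok] <- score_pc1(pca, feats[ok, ])
  attr(feats, "pca") <- pca
  feats
}

PIPELINE_VARS <- c("conspiracism", "llm_narrative_score", "lexicon_ratio",
                   "lexical_mean", "pc1", "cohesion", "megalalia",
                   "word_count", "education")

#' Run the full analysis pipeline
#'
#' Validates the configuration, loads every input, computes the feature
#' table, joins it to the participant table on `doc_id`, and writes
#' `features.tsv`, a correlation matrix over the trait, narrative, lexicon
#' and text-quality variables, moderated regressions predicting the lexicon
#' and narrative scores from conspiracism x textual quality, an optional
#' scramble-validation report, and `run.log`.
#'
#' @param config A `run_config` (or path to a YAML file for
#'   [read_run_config()]).
#' @return Invisibly, a list with `features`, `correlations`, `moderation`,
#'   `scramble` and `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  # validate before any computation
  needed <- c(corpus = config$corpus, lexicon = config$lexicon,
              norms = config$norms, participants = config$participants)
  if (config$scramble || !is.null(config$embeddings)) {
    if (is.null(config$embeddings)) {
      stop("cohesion/scramble enabled but no embeddings path configured")
    }
    needed <- c(needed, embeddings = config$embeddings)
  }
  if (!is.null(config$stopwords)) needed <- c(needed, stopwords = config$stopwords)
  missing_paths <- needed[!file.exists(needed)]
  if (length(missing_paths)) {
    stop("missing input path(s): ",
         paste(sprintf("%s (%s)", names(missing_paths), missing_paths),
               collapse = ", "))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in setdiff(names(config), "")) {
    v <- config[[k]]
    log("config %s = %s", k, if (is.null(v)) "NULL" else paste(v, collapse = ","))
  }

  docs <- read_conllu(config$corpus)
  lex <- read_lexicon(config$lexicon)
  norms <- read_norm_table(config$norms)
  emb <- if (!is.null(config$embeddings)) load_embeddings(config$embeddings)
  sw <- if (!is.null(config$stopwords)) read_stopwords(config$stopwords)
    else character(0)
  rules <- if (!is.null(config$compound_rules))
    read_compound_rules(config$compound_rules)
  participants <- utils::read.delim(config$participants,
                                    stringsAsFactors = FALSE)
  log("loaded %d documents, %d participants, %d lexicon entries",
      length(docs), nrow(participants), length(lex$entries))

  feats <- compute_features(docs, lex, norms, emb, sw, rules,
                            config$coverage_threshold)
  doc_ids <- feats$doc_id
  orphans_docs <- setdiff(doc_ids, participants$doc_id)
  orphans_part <- setdiff(participants$doc_id, doc_ids)
  if (length(orphans_docs) || length(orphans_part)) {
    msg <- sprintf("join failures: %d document(s) without participant [%s]; %d participant(s) without document [%s]",
                   length(orphans_docs), paste(utils::head(orphans_docs, 5), collapse = ","),
                   length(orphans_part), paste(utils::head(orphans_part, 5), collapse = ","))
    if (config$strict) stop(msg)
    log("%s; continuing with complete cases", msg)
  }
  joined <- merge(feats, participants, by = "doc_id")
  log("feature rows: %d (joined: %d)", nrow(feats), nrow(joined))

  con <- file(file.path(config$output_dir, "features.tsv"), open = "wb")
  write_tsv_con(joined, con); close(con)

  vars <- intersect(PIPELINE_VARS, names(joined))
  vars <- vars[vapply(vars, function(v)
    sum(!is.na(joined[[v]])) >= 4 && stats::sd(joined[[v]], na.rm = TRUE) > 0,
    TRUE)]
  cors <- NULL
  if (length(vars) >= 2L) {
    cors <- correlation_matrix(joined, vars)
    write_correlation_matrix(cors, file.path(config$output_dir,
                                             "correlations.tsv"))
    log("correlation matrix over: %s", paste(vars, collapse = ", "))
  }

  moderation <- NULL
  outcomes <- intersect(c("lexicon_ratio", "llm_narrative_score"), vars)
  moderators <- intersect(c("lexical_mean", "pc1", "cohesion"), vars)
  if ("conspiracism" %in% vars && length(outcomes) && length(moderators)) {
    rows <- list()
    for (out in outcomes) for (mod in moderators) {
      fit <- tryCatch(moderated_regression(joined[[out]],
                                           joined$conspiracism, joined[[mod]],
                                           labels = c("conspiracism", mod)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      cf <- fit$coefficients
      cf$outcome <- out
      cf$n <- fit$n
      rows[[length(rows) + 1L]] <- cf
    }
    if (length(rows)) {
      moderation <- do.call(rbind, rows)
      con <- file(file.path(config$output_dir, "moderation.tsv"), open = "wb")
      write_tsv_con(moderation, con); close(con)
      log("moderation models: %d outcomes x %d moderators",
          length(outcomes), length(moderators))
    }
  }

  scr <- NULL
  if (config$scramble) {
    scr <- tryCatch(
      scramble_validation(docs, emb, sw, min_sentences = config$min_sentences,
                          seed = config$seed),
      error = function(e) { log("scramble validation skipped: %s",
                                conditionMessage(e)); NULL })
    if (!is.null(scr)) {
      write_scramble_report(scr, file.path(config$output_dir,
                                           "scramble_report.tsv"))
      log("scramble validation: t(%.2f) = %.2f, p = %.3g, d = %.2f (%s)",
          scr$df, scr$t, scr$p, scr$d, scr$direction)
    }
  }
  log("seed = %d", config$seed)
  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  invisible(list(features = joined, correlations = cors,
                 moderation = moderation, scramble = scr, log = log_lines))
}
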