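# Synthetic-corpus generator: participants with latent conspiracism traits,
# parsed documents whose lexicon usage, sophistication spikes, syntax and
# topic structure carry planted, recoverable effects, plus matching norm
# tables, lexica, embeddings and stopword lists.

#' Configuration of the synthetic corpus generator
#'
#' Defaults emulate the study conditions the pipeline is meant for: a pooled
#' sample of 385 essay writers, a trait-lexicon correlation of .19, one essay
#' per participant with topic-coherent adjacent sentences, and a low rate of
#' sophisticated-word "spikes" that increases with the trait.
#'
#' @param n_participants Number of participants (one document each).
#' @param trait_mean,trait_sd Latent trait distribution before the 0-1
#'   squashing.
#' @param lexicon_effect_r Target correlation between the trait and the
#'   realized per-document lexicon usage rate.
#' @param base_lexicon_rate Mean probability that a content token is drawn
#'   from the lexicon.
#' @param n_common,n_sophisticated,n_lexicon,n_stopwords Vocabulary sizes per
#'   stratum.
#' @param norm_bounds Declared bounds of the generated norm scale.
#' @param common_norm_range,sophisticated_norm_range,lexicon_norm_range
#'   Sophistication-rating ranges per stratum (uniform draws).
#' @param sentences_per_doc,tokens_per_sentence Integer `c(min, max)` ranges.
#' @param verb_rate Probability that a content token is a verb or auxiliary.
#' @param p_long_head Probability that a token attaches to the sentence root
#'   instead of its left neighbour (drives dependency distance).
#' @param n_topics,topic_block_sentences Topic structure: adjacent sentences
#'   share a topic within blocks of this many sentences.
#' @param emb_dim,emb_noise_sd Embedding dimension and within-topic noise.
#' @param stopword_rate Probability that a token is a function word.
#' @param megalalia_spike_rate Base probability of a sophisticated-word
#'   spike; modulated by the trait via `spike_trait_slope`.
#' @param spike_trait_slope Logistic slope linking the standardized trait to
#'   the spike probability.
#' @param question_rate,exclaim_rate Probability a sentence ends in `?` / `!`.
#' @param num_rate Probability of a numeral token.
#' @param include_punct_in_lexicon Add `?` and `!` to the generated lexicon.
#' @param seed Mandatory integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 385,
                             trait_mean = 0, trait_sd = 1,
                             lexicon_effect_r = 0.19,
                             base_lexicon_rate = 0.10,
                             n_common = 120, n_sophisticated = 30,
                             n_lexicon = 50, n_stopwords = 30,
                             norm_bounds = c(1, 10),
                             common_norm_range = c(1, 3),
                             sophisticated_norm_range = c(7, 10),
                             lexicon_norm_range = c(3, 6),
                             sentences_per_doc = c(10, 30),
                             tokens_per_sentence = c(6, 14),
                             verb_rate = 0.22,
                             p_long_head = 0.3,
                             n_topics = 3,
                             topic_block_sentences = 5,
                             emb_dim = 50, emb_noise_sd = 0.3,
                             stopword_rate = 0.25,
                             megalalia_spike_rate = 0.04,
                             spike_trait_slope = 1,
                             question_rate = 0.05, exclaim_rate = 0.03,
                             num_rate = 0.02,
                             include_punct_in_lexicon = TRUE,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("synthetic_config: seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(base_lexicon_rate, verb_rate, p_long_head, stopword_rate,
             megalalia_spike_rate, question_rate, exclaim_rate, num_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (abs(lexicon_effect_r) >= 1) stop("lexicon_effect_r must lie in (-1, 1)")
  for (rng in list(norm_bounds, common_norm_range, sophisticated_norm_range,
                   lexicon_norm_range, sentences_per_doc,
                   tokens_per_sentence)) {
    if (length(rng) != 2L || rng[1] > rng[2]) stop("min/max range invalid")
  }
  for (rng in list(common_norm_range, sophisticated_norm_range,
                   lexicon_norm_range)) {
    if (rng[1] < norm_bounds[1] || rng[2] > norm_bounds[2]) {
      stop("stratum norm range outside declared norm bounds")
    }
  }
  if (n_participants < 2L) stop("need at least 2 participants")
  if (min(n_common, n_sophisticated, n_lexicon) < n_topics) {
    stop("infeasible config: each vocabulary stratum needs at least one lemma per topic")
  }
  structure(cfg, class = "synthetic_config")
}

# Logistic trait->rate calibration: choose intercept a so the mean content
# rate matches base_lexicon_rate, then root-search the slope b so the
# attenuation-corrected expected corpus correlation between the trait and
# the realized match ratio hits the target. The attenuation model includes
# the binomial noise of the lexicon draws and of the constant-rate `?`/`!`
# matches, both over the processed-token denominator.
calibrate_lexicon_link <- function(trait, target_r, base_rate, n_tokens,
                                   n_sent, content_frac, num_frac,
                                   punct_rate, punct_in_lexicon) {
  zc <- (trait - mean(trait)) / stats::sd(trait)
  n_content <- n_tokens * content_frac
  denom <- n_tokens * (1 - num_frac) + n_sent * punct_rate
  k_punct <- if (punct_in_lexicon) n_sent * punct_rate else 0
  solve_a <- function(b) {
    span <- 15 + abs(b) * (max(abs(zc)) + 1)
    stats::uniroot(function(a) mean(stats::plogis(a + b * zc)) - base_rate,
                   interval = stats::qlogis(base_rate) + c(-span, span))$root
  }
  expected_r <- function(b) {
    if (abs(b) < 1e-12) return(0)
    p <- stats::plogis(solve_a(b) + b * zc)
    m <- (n_content * p + k_punct) / denom   # expected match ratio
    v <- stats::var(m)
    if (v == 0) return(0)
    noise <- (n_content * p * (1 - p) +
                k_punct * (1 - punct_rate)) / denom^2
    stats::cor(trait, m) * sqrt(v / (v + mean(noise)))
  }
  if (abs(target_r) < 1e-8) {
    b <- 0
  } else {
    s <- sign(target_r)
    hi <- 30
    if (s * expected_r(s * hi) < abs(target_r)) {
      stop("lexicon_effect_r unreachable under this configuration")
    }
    b <- stats::uniroot(function(b) expected_r(b) - target_r,
                        interval = sort(c(s * 1e-6, s * hi)))$root
  }
  list(a = solve_a(b), b = b, zc = zc)
}

rint <- function(n, rng) {
  if (rng[1] == rng[2]) rep(as.integer(rng[1]), n)
  else sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
}

# One sentence of token rows. lemma_draw(class) supplies a lemma for classes
# "stop", "lex", "spike", "common"; probabilities are per content token.
build_sentence <- function(n_tokens, verb_rate, p_long, lemma_draw,
                           stopword_rate, p_lex, p_spike, num_rate,
                           question_rate, exclaim_rate) {
  lemmas <- character(n_tokens)
  upos <- character(n_tokens)
  for (i in seq_len(n_tokens)) {
    u <- stats::runif(1)
    if (u < stopword_rate) {
      lemmas[i] <- lemma_draw("stop")
      upos[i] <- sample(c("DET", "ADP", "PRON", "CCONJ"), 1)
    } else if (u < stopword_rate + num_rate) {
      lemmas[i] <- as.character(sample.int(999L, 1))
      upos[i] <- "NUM"
    } else {
      v <- stats::runif(1)
      cls <- if (v < p_lex) "lex" else if (v < p_lex + p_spike) "spike"
             else "common"
      lemmas[i] <- lemma_draw(cls)
      uv <- stats::runif(1)
      upos[i] <- if (uv < verb_rate * 0.75) "VERB"
                 else if (uv < verb_rate) "AUX"
                 else sample(c("NOUN", "ADJ", "ADV", "PROPN"), 1,
                             prob = c(.5, .2, .15, .15))
    }
  }
  up <- stats::runif(1)
  final <- if (up < question_rate) "?" else if (up < question_rate +
                                                exclaim_rate) "!" else "."
  lemmas <- c(lemmas, final)
  upos <- c(upos, "PUNCT")
  m <- length(lemmas)
  head <- c(NA_integer_, vapply(seq_len(m - 1L), function(i) {
    if (stats::runif(1) < p_long) 0L else i - 1L
  }, 0L))
  surface <- lemmas
  substr(surface[1], 1, 1) <- toupper(substr(surface[1], 1, 1))
  data.frame(index = seq_len(m) - 1L, surface = surface, lemma = lemmas,
             upos = upos, head = head, stringsAsFactors = FALSE)
}

#' Generate a synthetic corpus with planted statistical structure
#'
#' Draws one participant trait and one parsed document per participant. The
#' probability that a content token comes from the conspiratorial lexicon is
#' a logistic function of the standardized trait, calibrated so that the
#' realized corpus correlation between the trait and the lexicon match ratio
#' approaches `lexicon_effect_r`. Sophisticated-word spikes (which drive
#' megalalia) increase with the trait. Sentences share embedding topics in
#' blocks, so original documents are more cohesive than scrambled ones.
#' Dependency heads follow the configured distance profile and verbs are
#' placed at `verb_rate`. All draws come from the seeded generator.
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_corpus`: list with `participants` (data frame),
#'   `docs` (list of `parsed_document`), `norms`, `lexicon`, `embeddings`,
#'   `stopwords`, `calibration` and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_participants
    z <- stats::rnorm(n, cfg$trait_mean, cfg$trait_sd)

    # trait instruments: an 11-item 1-7 scale and a 15-item 1-5 scale,
    # scored through the scales module so the composite path is exercised
    cms <- scale_spec("CMS", 11, 1, 7)
    gcb <- scale_spec("GCB", 15, 1, 5)
    n1 <- max(1L, round(n * 285 / 385))
    study <- c(rep("study1", n1), rep("study2", n - n1))
    max_items <- max(cms$n_items, gcb$n_items)
    resp <- matrix(NA_integer_, n, max_items,
                   dimnames = list(NULL, sprintf("item_%02d", 1:max_items)))
    conspiracism <- numeric(n)
    for (i in seq_len(n)) {
      sp <- if (study[i] == "study1") cms else gcb
      centre <- sp$likert_min + stats::plogis(z[i]) *
        (sp$likert_max - sp$likert_min)
      noise_sd <- 0.18 * (sp$likert_max - sp$likert_min)
      r <- clamp(round(centre + stats::rnorm(sp$n_items, 0, noise_sd)),
                 sp$likert_min, sp$likert_max)
      resp[i, seq_len(sp$n_items)] <- as.integer(r)
      conspiracism[i] <- as.numeric(composite_conspiracism(as.integer(r), sp))
    }
    education <- as.integer(clamp(round(3.2 - 0.4 * z +
                                          stats::rnorm(n, 0, 0.9)), 1, 5))
    age <- as.integer(round(clamp(stats::rnorm(n, 24, 6), 18, 70)))
    llm_narrative_score <- round(clamp(5 + 0.2 * z + stats::rnorm(n, 0, 2),
                                       0, 10), 3)
    participants <- data.frame(
      pid = sprintf("p%04d", seq_len(n)), doc_id = sprintf("d%04d", seq_len(n)),
      study = study, scale = ifelse(study == "study1", "CMS", "GCB"),
      age = age, education = education,
      conspiracism = conspiracism, llm_narrative_score = llm_narrative_score,
      stringsAsFactors = FALSE)
    participants <- cbind(participants, as.data.frame(resp))

    # vocabulary strata, topic assignments, norms
    stopwords <- sprintf("fw%02d", seq_len(cfg$n_stopwords))
    common <- sprintf("w%03d", seq_len(cfg$n_common))
    soph <- sprintf("x%03d", seq_len(cfg$n_sophisticated))
    lexw <- sprintf("c%03d", seq_len(cfg$n_lexicon))
    topic_of <- function(words) rep_len(seq_len(cfg$n_topics), length(words))
    topics <- c(stats::setNames(topic_of(common), common),
                stats::setNames(topic_of(soph), soph),
                stats::setNames(topic_of(lexw), lexw))
    runif_rng <- function(k, rng) stats::runif(k, rng[1], rng[2])
    ratings <- c(
      stats::setNames(runif_rng(length(stopwords), cfg$common_norm_range), stopwords),
      stats::setNames(runif_rng(length(common), cfg$common_norm_range), common),
      stats::setNames(runif_rng(length(soph), cfg$sophisticated_norm_range), soph),
      stats::setNames(runif_rng(length(lexw), cfg$lexicon_norm_range), lexw))
    norms <- norm_table(round(ratings, 4), cfg$norm_bounds[1], cfg$norm_bounds[2])
    lex_entries <- if (cfg$include_punct_in_lexicon) c(lexw, "?", "!") else lexw
    lex <- lexicon(lex_entries, name = "synthetic_conspiracy")

    # embeddings: topic centroid + isotropic noise; stopwords off-topic
    centroids <- matrix(stats::rnorm(cfg$n_topics * cfg$emb_dim), cfg$n_topics)
    content_words <- names(topics)
    V <- centroids[topics[content_words], , drop = FALSE] +
      matrix(stats::rnorm(length(content_words) * cfg$emb_dim, 0,
                          cfg$emb_noise_sd), length(content_words))
    S <- matrix(stats::rnorm(cfg$n_stopwords * cfg$emb_dim), cfg$n_stopwords)
    M <- round(rbind(V, S), 6)
    rownames(M) <- c(content_words, stopwords)
    emb <- embedding_table(M)

    # plan document sizes, then calibrate the trait->lexicon link
    n_sent <- rint(n, cfg$sentences_per_doc)
    exp_tokens <- n_sent * mean(cfg$tokens_per_sentence)
    cal <- calibrate_lexicon_link(
      conspiracism, cfg$lexicon_effect_r, cfg$base_lexicon_rate, exp_tokens,
      n_sent = n_sent,
      content_frac = 1 - cfg$stopword_rate - cfg$num_rate,
      num_frac = cfg$num_rate,
      punct_rate = cfg$question_rate + cfg$exclaim_rate,
      punct_in_lexicon = cfg$include_punct_in_lexicon)
    p_lex <- stats::plogis(cal$a + cal$b * cal$zc)
    p_spike <- pmin(0.9, 2 * cfg$megalalia_spike_rate *
                      stats::plogis(cfg$spike_trait_slope * cal$zc))

    by_topic <- function(words) split(words, topics[words])
    pool <- list(common = by_topic(common), spike = by_topic(soph),
                 lex = by_topic(lexw))
    docs <- vector("list", n)
    for (i in seq_len(n)) {
      ns <- n_sent[i]
      n_blocks <- ceiling(ns / cfg$topic_block_sentences)
      bt <- integer(n_blocks)
      bt[1] <- sample.int(cfg$n_topics, 1)
      if (n_blocks > 1) for (b in 2:n_blocks) {
        bt[b] <- if (cfg$n_topics == 1) 1L else
          sample(setdiff(seq_len(cfg$n_topics), bt[b - 1]), 1)
      }
      sent_topic <- rep(bt, each = cfg$topic_block_sentences)[seq_len(ns)]
      sents <- vector("list", ns)
      for (s in seq_len(ns)) {
        tp <- as.character(sent_topic[s])
        draw <- function(cls) {
          if (cls == "stop") return(sample(stopwords, 1))
          p <- pool[[cls]][[tp]]
          if (length(p) == 1L) p else sample(p, 1)
        }
        df <- build_sentence(rint(1, cfg$tokens_per_sentence), cfg$verb_rate,
                             cfg$p_long_head, draw, cfg$stopword_rate,
                             p_lex[i], p_spike[i], cfg$num_rate,
                             cfg$question_rate, cfg$exclaim_rate)
        df$sentence <- s
        sents[[s]] <- df
      }
      docs[[i]] <- parsed_document(participants$doc_id[i],
                                   do.call(rbind, sents))
    }
    structure(list(participants = participants, docs = docs, norms = norms,
                   lexicon = lex, embeddings = emb, stopwords = stopwords,
                   calibration = cal[c("a", "b")], config = cfg),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d participants/documents, %d-entry lexicon, dim-%d embeddings>\n",
              length(x$docs), length(x$lexicon$entries), x$embeddings$dim))
  invisible(x)
}

#' Generate a high- vs low-syntactic-complexity contrast corpus
#'
#' Two labelled arms for validating the syntactic-sophistication composite:
#' the high arm has long sentences, many verbs and long head distances; the
#' low arm the opposite. The generator only fixes the sampling profiles — the
#' composite itself is estimated downstream.
#'
#' @param n_docs Total number of documents (split evenly; must be >= 4).
#' @param seed Integer seed.
#' @param high,low Per-arm profiles: lists with `tokens_per_sentence`
#'   (`c(min, max)`), `verb_rate`, `p_long_head`.
#' @param sentences_per_doc Sentence-count range shared by both arms.
#' @return List with `docs` (parsed documents) and `labels`
#'   (`"high"`/`"low"`).
#' @export
generate_complexity_contrast <- function(
    n_docs = 50, seed,
    high = list(tokens_per_sentence = c(18, 28), verb_rate = 0.35,
                p_long_head = 0.6),
    low = list(tokens_per_sentence = c(5, 9), verb_rate = 0.12,
               p_long_head = 0.08),
    sentences_per_doc = c(8, 12)) {
  if (n_docs < 4L) stop("generate_complexity_contrast requires n_docs >= 4")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  vocab <- sprintf("g%03d", 1:80)
  with_seed(seed, {
    n_high <- n_docs %/% 2L
    labels <- c(rep("high", n_high), rep("low", n_docs - n_high))
    docs <- vector("list", n_docs)
    for (i in seq_len(n_docs)) {
      prof <- if (labels[i] == "high") high else low
      ns <- rint(1, sentences_per_doc)
      sents <- vector("list", ns)
      for (s in seq_len(ns)) {
        df <- build_sentence(rint(1, prof$tokens_per_sentence),
                             prof$verb_rate, prof$p_long_head,
                             function(cls) sample(vocab, 1),
                             stopword_rate = 0, p_lex = 0, p_spike = 0,
                             num_rate = 0, question_rate = 0,
                             exclaim_rate = 0)
        df$sentence <- s
        sents[[s]] <- df
      }
      docs[[i]] <- parsed_document(sprintf("%s%03d", labels[i], i),
                                   do.call(rbind, sents))
    }
    list(docs = docs, labels = labels)
  })
}

#' Write a synthetic corpus to a self-contained input directory
#'
#' Emits every format the pipeline consumes: `corpus.conllu`, `lexicon.txt`,
#' `norms.tsv`, `embeddings.vec`, `stopwords.txt`, `participants.tsv`.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_dir <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_conllu(corpus$docs, file.path(dir, "corpus.conllu"))
  con <- file(file.path(dir, "lexicon.txt"), open = "wb")
  writeLines(corpus$lexicon$entries, con, useBytes = TRUE)
  close(con)
  write_norm_table(corpus$norms, file.path(dir, "norms.tsv"))
  write_embeddings(corpus$embeddings, file.path(dir, "embeddings.vec"))
  con <- file(file.path(dir, "stopwords.txt"), open = "wb")
  writeLines(corpus$stopwords, con, useBytes = TRUE)
  close(con)
  con <- file(file.path(dir, "participants.tsv"), open = "wb")
  write_tsv_con(corpus$participants, con)
  close(con)
  invisible(dir)
}
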