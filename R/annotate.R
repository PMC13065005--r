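#' Build a run configuration
#'
#' Collects everything a pipeline run depends on — resource paths, the
#' thresholds, the rule dialects, the stopword toggle and the seed — into a
#' validated object whose fingerprint is stamped into every output file,
#' so two annotation runs are comparable exactly when their fingerprints
#' match.
#'
#' @param tagger tagger backend name; `"fixture"` (bundled gold tags +
#'   deterministic heuristic fallback) is the packaged backend, any other
#'   name is an adapter slot the caller must resolve via the `tagger`
#'   argument of [build_pipeline()]
#' @param vocabulary path to the condition vocabulary word list
#' @param sentiment_lexicon path to the sentiment lexicon TSV
#' @param strong,weak,negatives paths to the modifier word lists
#' @param thresholds a [thresholds()] object
#' @param extraction_mode `"strict"` or `"as_printed"`
#' @param polarity_mode `"calibrated"` or `"as_printed"`
#' @param remove_stopwords logical stopword toggle (default `FALSE`)
#' @param embedder_dim,embedder_seed hash-embedder parameters
#' @param seed integer seed for every source of randomness in a run
#' @param condition optional condition name
#' @return a `run_config` list with a `fingerprint` element
#' @export
run_config <- function(tagger = "fixture",
                       vocabulary = ext_file("vocab_depression.txt"),
                       sentiment_lexicon = ext_file("sentiment_lexicon.tsv"),
                       strong = ext_file("strong.txt"),
                       weak = ext_file("weak.txt"),
                       negatives = ext_file("negatives.txt"),
                       thresholds = aspectrx::thresholds(),
                       extraction_mode = c("strict", "as_printed"),
                       polarity_mode = c("calibrated", "as_printed"),
                       remove_stopwords = FALSE,
                       embedder_dim = 64L,
                       embedder_seed = 0L,
                       seed = 1L,
                       condition = "depression") {
  extraction_mode <- match.arg(extraction_mode)
  polarity_mode <- match.arg(polarity_mode)
  stopifnot(inherits(thresholds, "thresholds"), is.logical(remove_stopwords))
  for (p in c(vocabulary, sentiment_lexicon, strong, weak, negatives)) {
    if (!file.exists(p)) {
      stop_aspectrx(paste0("configured resource missing: ", p),
                    "aspectrx_config_error")
    }
  }
  cfg <- list(
    tagger = tagger, vocabulary = vocabulary,
    sentiment_lexicon = sentiment_lexicon,
    strong = strong, weak = weak, negatives = negatives,
    thresholds = unclass(thresholds),
    extraction_mode = extraction_mode, polarity_mode = polarity_mode,
    remove_stopwords = remove_stopwords,
    embedder_dim = as.integer(embedder_dim),
    embedder_seed = as.integer(embedder_seed),
    seed = as.integer(seed), condition = condition
  )
  lex_hash <- vapply(
    c(cfg$vocabulary, cfg$sentiment_lexicon, cfg$strong, cfg$weak,
      cfg$negatives),
    function(p) fnv1a32(readLines(p, warn = FALSE)), character(1)
  )
  core <- cfg
  core[c("vocabulary", "sentiment_lexicon", "strong", "weak",
         "negatives")] <- NULL
  cfg$fingerprint <- fnv1a32(c(
    paste(names(unlist(core)), unlist(core), sep = "="),
    unname(lex_hash)
  ))
  class(cfg) <- "run_config"
  cfg
}

#' Resolve a run configuration into a ready pipeline
#'
#' Loads the lexicons and vocabulary, instantiates the embedder and the
#' tagger, and returns the bundle that [annotate_review()] consumes.
#'
#' @param config a [run_config()]
#' @param gold_tags optional extra gold-tag table handed to
#'   [fixture_tagger()] (e.g. from [generate_corpus()])
#' @param tagger optional tagger function overriding the configured backend
#' @param embedder optional embedder overriding the hash embedder
#' @param vocab optional [medical_vocabulary()] overriding the configured
#'   vocabulary file (e.g. the `$vocabulary` of a generated corpus)
#' @return a `pipeline` list
#' @export
build_pipeline <- function(config = run_config(), gold_tags = NULL,
                           tagger = NULL, embedder = NULL, vocab = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(tagger)) {
    if (!identical(config$tagger, "fixture")) {
      stop_aspectrx(
        paste0("no adapter registered for tagger backend '", config$tagger,
               "'; pass one via the tagger argument"),
        "aspectrx_config_error"
      )
    }
    tagger <- fixture_tagger(gold = gold_tags)
  }
  modlex <- modifier_lexicon(config$strong, config$weak, config$negatives,
                             from_files = TRUE)
  structure(list(
    config = config,
    tagger = tagger,
    modlex = modlex,
    sentlex = sentiment_lexicon(config$sentiment_lexicon),
    vocab = vocab %||% load_vocabulary(config$vocabulary, config$condition),
    embedder = embedder %||% hash_embedder(dim = config$embedder_dim,
                                           seed = config$embedder_seed),
    thresholds = do.call(thresholds, config$thresholds),
    stopword_keep = unique(unlist(modlex))
  ), class = "pipeline")
}

#' Annotate one review
#'
#' Runs the full scheme on a single review: normalization, sentence
#' segmentation, tagging, rule-based candidate extraction, vocabulary
#' filtering, polarity scoring and labelling. Every kept aspect in a
#' sentence receives that sentence's label. A sentence whose tagging fails
#' is recorded as skipped with its reason; the review itself is never
#' dropped.
#'
#' @param review a list/row with `review_id`, `drug_name`, `condition`,
#'   `text`
#' @param pipeline a [build_pipeline()] result
#' @return an `annotation_record` list
#' @export
annotate_review <- function(review, pipeline) {
  stopifnot(inherits(pipeline, "pipeline"))
  cfg <- pipeline$config
  text <- normalize_text(as.character(review$text %||% ""),
                         remove_stopwords = cfg$remove_stopwords,
                         keep = pipeline$stopword_keep)
  sents <- split_sentences(text)
  entries <- vector("list", length(sents))
  for (si in seq_along(sents)) {
    sid <- paste0(review$review_id, ":s", si)
    entry <- list(sentence_id = sid, text = sents[si])
    ts <- tryCatch(tag_sentence(sents[si], pipeline$tagger, sentence_id = sid),
                   aspectrx_tagging_error = function(e) e)
    if (inherits(ts, "error")) {
      entry$skipped <- conditionMessage(ts)
      entry$tokens <- list()
      entry$aspects <- list()
      entry$polarity <- 0
      entry$label <- "no_opinion"
      entries[[si]] <- entry
      next
    }
    cands <- extract_candidates(ts, mode = cfg$extraction_mode)
    scored <- filter_candidates(cands, pipeline$vocab, pipeline$embedder,
                                threshold = pipeline$thresholds$sim_threshold)
    kept <- scored[scored$kept, , drop = FALSE]
    state <- detect_polarity(ts, candidate_indices(kept), pipeline$modlex,
                             pipeline$sentlex, pipeline$thresholds,
                             mode = cfg$polarity_mode)
    label <- classify_label(state, pipeline$thresholds)
    entry$tokens <- as.list(ts$surface)
    entry$aspects <- lapply(seq_len(nrow(kept)), function(k) {
      idx <- c(kept$idx1[k], kept$idx2[k])
      list(surface = kept$surface[k],
           indices = as.list(idx[!is.na(idx)]),
           rule = kept$rule[k],
           similarity = kept$score[k])
    })
    entry$polarity <- state$polarity
    entry$label <- label
    entries[[si]] <- entry
  }
  structure(list(
    review_id = as.character(review$review_id),
    drug_name = as.character(review$drug_name %||% ""),
    condition = as.character(review$condition %||% ""),
    sentences = entries,
    fingerprint = cfg$fingerprint
  ), class = "annotation_record")
}

#' Annotate a corpus of reviews
#'
#' @param reviews data.frame from [read_reviews()] (columns `review_id`,
#'   `drug_name`, `condition`, `text`)
#' @param pipeline a [build_pipeline()] result
#' @return list of `annotation_record`s
#' @export
annotate_corpus <- function(reviews, pipeline) {
  lapply(seq_len(nrow(reviews)),
         function(i) annotate_review(reviews[i, ], pipeline))
}
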