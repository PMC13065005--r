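# Deterministic generators for offline testing: a synthetic review corpus
# with aspects planted through the three extraction patterns, opinion words
# with a configurable sentiment-class mix, modifier/negation insertions and
# out-of-vocabulary distractor nouns.

syn_inventory <- list(
  single_nouns = c("anxiety", "nausea", "insomnia", "headache", "fatigue",
                   "dizziness", "appetite", "libido", "energy", "pain"),
  pair_terms = c("mood swings", "side effects", "side affects",
                 "panic attacks", "weight gain", "brain zaps"),
  licensing_adjs = c("depressive", "chronic", "mental", "physical",
                     "hormonal"),
  distractor_nouns = c("sofa", "carpet", "television", "weather", "traffic",
                       "keyboard", "garden", "bicycle", "wallet", "ceiling"),
  distractor_pairs = c("coffee table", "parking lot", "phone screen"),
  # positive-side opinion adjectives by raw lexicon pos score
  pos_words = c(wonderful = 0.8, helpful = 0.8, effective = 0.75,
                good = 0.75),
  # negative-side opinion adjectives by raw lexicon neg score
  neg_words = c(awful = 0.8, terrible = 0.85, bad = 0.7),
  # words whose squared pos score stays inside the neutral band
  neutral_words = c(positive = 0.7, good = 0.75, effective = 0.75),
  drugs = c("alphadrin", "betazol", "gammaline", "deltaprex")
)

#' Specify a synthetic review corpus
#'
#' Defines the study conditions a generated corpus emulates: how many
#' reviews, which extraction pattern plants each aspect, how often strong /
#' weak / negation modifiers are inserted, the sentiment-class mix, and the
#' rate of out-of-vocabulary distractor nouns. The default class mix
#' follows the observed Depression-condition distribution of aspect phrases
#' (about 21% positive, 48% negative, 31% carrying no opinion); neutral
#' sentences are planted as a weak modifier over a strong positive opinion
#' word, so a neutral share requires a non-empty weak-modifier inventory.
#'
#' @param n_reviews number of reviews
#' @param condition condition name stamped on every review
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   the spec)
#' @param pattern_rates named probabilities over
#'   `single_noun` / `compound_pair` / `adj_licensed` (normalized)
#' @param modifier_probs named insertion probabilities `strong`, `weak`,
#'   `negation` for positive/negative sentences
#' @param class_mix named mix over `positive`, `negative`, `neutral`,
#'   `no_opinion` (normalized)
#' @param distractor_rate probability a sentence also carries a planted
#'   out-of-vocabulary distractor aspect
#' @param sentences_per_review sentences per review
#' @param modifiers list with character vectors `strong`, `weak`,
#'   `negation`: the modifier words the generator may insert (defaults to a
#'   subset of the bundled modifier lexicon)
#' @return a `corpus_spec` list
#' @export
corpus_spec <- function(n_reviews,
                        condition = "depression",
                        seed,
                        pattern_rates = c(single_noun = 1 / 3,
                                          compound_pair = 1 / 3,
                                          adj_licensed = 1 / 3),
                        modifier_probs = c(strong = 0.1, weak = 0.1,
                                           negation = 0.1),
                        class_mix = c(positive = 4243, negative = 9442,
                                      neutral = 0, no_opinion = 6148) / 19833,
                        distractor_rate = 0.3,
                        sentences_per_review = 2L,
                        modifiers = syn_modifiers()) {
  if (missing(seed)) {
    stop_aspectrx("corpus_spec requires a seed", "aspectrx_config_error")
  }
  stopifnot(n_reviews >= 0, sentences_per_review >= 1)
  pr <- pattern_rates[c("single_noun", "compound_pair", "adj_licensed")]
  cm <- class_mix[c("positive", "negative", "neutral", "no_opinion")]
  cm[is.na(cm)] <- 0
  if (any(is.na(pr)) || any(pr < 0) || sum(pr) <= 0) {
    stop_aspectrx("pattern_rates must be non-negative and name all three patterns",
                  "aspectrx_config_error")
  }
  mp <- modifier_probs[c("strong", "weak", "negation")]
  if (any(is.na(mp)) || any(mp < 0 | mp > 1)) {
    stop_aspectrx("modifier_probs must be probabilities for strong/weak/negation",
                  "aspectrx_config_error")
  }
  if (any(cm < 0) || sum(cm) <= 0) {
    stop_aspectrx("class_mix must be non-negative and not all zero",
                  "aspectrx_config_error")
  }
  stopifnot(is.list(modifiers),
            all(c("strong", "weak", "negation") %in% names(modifiers)))
  if (cm[["neutral"]] > 0 && !length(modifiers$weak)) {
    stop_aspectrx("a neutral class share requires weak modifiers",
                  "aspectrx_config_error")
  }
  for (m in c("strong", "weak", "negation")) {
    key <- if (m == "negation") "negation" else m
    if (mp[[key]] > 0 && !length(modifiers[[m]])) {
      stop_aspectrx(paste0(m, " insertions require ", m, " modifier words"),
                    "aspectrx_config_error")
    }
  }
  stopifnot(distractor_rate >= 0, distractor_rate <= 1)
  structure(list(
    n_reviews = as.integer(n_reviews), condition = condition,
    seed = as.integer(seed),
    pattern_rates = pr / sum(pr),
    modifier_probs = mp,
    class_mix = cm / sum(cm),
    distractor_rate = distractor_rate,
    sentences_per_review = as.integer(sentences_per_review),
    modifiers = modifiers
  ), class = "corpus_spec")
}

# modifier words the generator inserts (a subset of the bundled lexicon)
syn_modifiers <- function() {
  list(strong = c("truly", "extremely"), weak = c("quite", "somewhat"),
       negation = c("not", "never"))
}

tok <- function(surface, pos, dep) {
  data.frame(surface = surface, pos = pos, dep = dep,
             stringsAsFactors = FALSE)
}

# aspect segment for one pattern; returns tokens + the planted surface
syn_aspect_segment <- function(pattern, in_vocab) {
  inv <- syn_inventory
  if (pattern == "single_noun") {
    noun <- if (in_vocab) sample(inv$single_nouns, 1)
            else sample(inv$distractor_nouns, 1)
    dep <- sample(c("ROOT", "nmod"), 1)
    list(tokens = rbind(tok("my", "OTHER", "det"), tok(noun, "NOUN", dep)),
         surface = noun, aspect_at = 2L)
  } else if (pattern == "compound_pair") {
    term <- if (in_vocab) sample(inv$pair_terms, 1)
            else sample(inv$distractor_pairs, 1)
    ws <- strsplit(term, " ")[[1]]
    list(tokens = rbind(tok("my", "OTHER", "det"),
                        tok(ws[1], "NOUN", "compound"),
                        tok(ws[2], "NOUN", "dobj")),
         surface = term, aspect_at = c(2L, 3L))
  } else {
    adj <- sample(inv$licensing_adjs, 1)
    noun <- if (in_vocab) sample(inv$single_nouns, 1)
            else sample(inv$distractor_nouns, 1)
    list(tokens = rbind(tok("my", "OTHER", "det"),
                        tok(adj, "ADJ", "amod"),
                        tok(noun, "NOUN", "dobj")),
         surface = noun, aspect_at = 3L)
  }
}

# opinion segment realizing a sentiment class; returns tokens + modifier use
syn_opinion_segment <- function(class, modifier_probs,
                                mods = syn_modifiers()) {
  inv <- syn_inventory
  feels <- tok("feels", "VERB", "dep")
  if (class == "no_opinion") {
    return(list(tokens = rbind(tok("since", "OTHER", "mark"),
                               tok("last", "ADJ", "dep"),
                               tok("week", "NOUN", "pobj")),
                has_modifier = FALSE))
  }
  if (class == "neutral") {
    w <- sample(names(inv$neutral_words), 1)
    return(list(tokens = rbind(feels, tok(sample(mods$weak, 1), "ADV", "advmod"),
                               tok(w, "ADJ", "acomp")),
                has_modifier = TRUE))
  }
  use_strong <- stats::runif(1) < modifier_probs[["strong"]]
  use_weak <- !use_strong && stats::runif(1) < modifier_probs[["weak"]]
  use_neg <- stats::runif(1) < modifier_probs[["negation"]]
  # negation realizes the class by flipping an opposite-side opinion word;
  # it replaces any strong/weak insertion (one flag, last writer wins)
  if (use_neg) {
    w <- if (class == "positive") sample(names(inv$neg_words), 1)
         else sample(names(inv$pos_words), 1)
    return(list(tokens = rbind(feels,
                               tok(sample(mods$negation, 1), "ADV", "neg"),
                               tok(w, "ADJ", "acomp")),
                has_modifier = TRUE))
  }
  if (class == "positive") {
    # under a weak modifier only words with squared score above the band
    w <- if (use_weak) sample(c("wonderful", "helpful"), 1)
         else sample(names(inv$pos_words), 1)
  } else {
    # under a weak modifier only words whose boosted flip stays below it
    w <- if (use_weak) sample(c("awful", "terrible"), 1)
         else sample(names(inv$neg_words), 1)
  }
  mod_tok <- if (use_strong) tok(sample(mods$strong, 1), "ADV", "advmod")
             else if (use_weak) tok(sample(mods$weak, 1), "ADV", "advmod")
             else NULL
  list(tokens = rbind(feels, mod_tok, tok(w, "ADJ", "acomp")),
       has_modifier = use_strong || use_weak)
}

#' Generate a synthetic drug-review corpus with gold annotations
#'
#' Fully deterministic given the spec: builds template sentences whose
#' aspects conform to the POS/dependency signature of one of the three
#' extraction patterns, realizes the drawn sentiment class through opinion
#' words (and, when drawn, modifier or negation insertions that preserve
#' the intended label), and plants out-of-vocabulary distractor nouns at
#' the configured rate. Returns CSV-writable review rows, the gold-tag
#' table to register with [fixture_tagger()], per-sentence gold
#' annotations, and the in-vocabulary term list.
#'
#' @param spec a [corpus_spec()]
#' @return list with components `reviews` (data.frame `review_id`,
#'   `drugName`, `condition`, `review`), `tags` (gold-tag table), `gold`
#'   (data.frame: `review_id`, `sentence_id`, `surface`, `rule`,
#'   `in_vocab`, `intended_label`, `has_modifier`), `vocabulary`
#'   (character), `sentences` (data.frame `sentence_id`, `text`)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_local_seed(spec$seed, function() generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  inv <- syn_inventory
  reviews <- list()
  tags <- list()
  gold <- list()
  sent_tab <- list()
  classes <- names(spec$class_mix)
  patterns <- names(spec$pattern_rates)

  for (ri in seq_len(spec$n_reviews)) {
    rid <- sprintf("syn%04d", ri)
    sent_texts <- character(spec$sentences_per_review)
    for (si in seq_len(spec$sentences_per_review)) {
      sid <- sprintf("%s:s%d", rid, si)
      pattern <- sample(patterns, 1, prob = spec$pattern_rates)
      class <- sample(classes, 1, prob = spec$class_mix)
      asp <- syn_aspect_segment(pattern, in_vocab = TRUE)
      op <- syn_opinion_segment(class, spec$modifier_probs, spec$modifiers)
      toks <- rbind(asp$tokens, op$tokens)
      gold[[length(gold) + 1L]] <- data.frame(
        review_id = rid, sentence_id = sid, surface = asp$surface,
        rule = pattern, in_vocab = TRUE, intended_label = class,
        has_modifier = op$has_modifier, stringsAsFactors = FALSE
      )
      if (stats::runif(1) < spec$distractor_rate) {
        dpat <- sample(patterns, 1, prob = spec$pattern_rates)
        dst <- syn_aspect_segment(dpat, in_vocab = FALSE)
        toks <- rbind(toks, dst$tokens)
        gold[[length(gold) + 1L]] <- data.frame(
          review_id = rid, sentence_id = sid, surface = dst$surface,
          rule = dpat, in_vocab = FALSE, intended_label = class,
          has_modifier = op$has_modifier, stringsAsFactors = FALSE
        )
      }
      toks <- rbind(toks, tok(".", "OTHER", "punct"))
      tags[[length(tags) + 1L]] <- data.frame(
        sentence_id = sid, index = seq_len(nrow(toks)) - 1L,
        surface = toks$surface, pos = toks$pos, dep = toks$dep,
        stringsAsFactors = FALSE
      )
      sent_texts[si] <- paste(toks$surface, collapse = " ")
      sent_tab[[length(sent_tab) + 1L]] <- data.frame(
        sentence_id = sid, text = sent_texts[si], stringsAsFactors = FALSE
      )
    }
    reviews[[ri]] <- data.frame(
      review_id = rid,
      drugName = sample(inv$drugs, 1),
      condition = spec$condition,
      review = paste(sent_texts, collapse = " "),
      stringsAsFactors = FALSE
    )
  }

  list(
    reviews = if (length(reviews)) do.call(rbind, reviews) else
      data.frame(review_id = character(), drugName = character(),
                 condition = character(), review = character()),
    tags = if (length(tags)) do.call(rbind, tags) else
      data.frame(sentence_id = character(), index = integer(),
                 surface = character(), pos = character(),
                 dep = character()),
    gold = if (length(gold)) do.call(rbind, gold) else
      data.frame(review_id = character(), sentence_id = character(),
                 surface = character(), rule = character(),
                 in_vocab = logical(), intended_label = character(),
                 has_modifier = logical()),
    vocabulary = sort(unique(c(inv$single_nouns, inv$pair_terms))),
    sentences = if (length(sent_tab)) do.call(rbind, sent_tab) else
      data.frame(sentence_id = character(), text = character())
  )
}
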