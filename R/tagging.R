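#' Construct a tagged sentence
#'
#' The unit the rule engines consume: an ordered token table with surface
#' form, coarse part-of-speech and dependency label per token. Token indices
#' are 0-based and gap-free.
#'
#' @param surface character vector of token surfaces
#' @param pos character vector of coarse POS tags; anything outside
#'   `c("NOUN","ADJ","ADV","VERB")` is mapped to `"OTHER"` via
#'   [map_upos()]
#' @param dep character vector of dependency labels (passed through; empty
#'   or NA becomes `"dep"`)
#' @param sentence_id opaque identifier
#' @return a `tagged_sentence`: data.frame with columns `index`, `surface`,
#'   `pos`, `dep` and attribute `sentence_id`
#' @export
tagged_sentence <- function(surface, pos, dep, sentence_id = "s1") {
  stopifnot(length(surface) == length(pos), length(pos) == length(dep))
  pos <- map_upos(pos)
  dep <- as.character(dep)
  dep[is.na(dep) | !nzchar(dep)] <- "dep"
  out <- data.frame(
    index = seq_along(surface) - 1L,
    surface = as.character(surface),
    pos = pos,
    dep = dep,
    stringsAsFactors = FALSE
  )
  attr(out, "sentence_id") <- sentence_id
  class(out) <- c("tagged_sentence", "data.frame")
  out
}

coarse_pos_set <- c("NOUN", "ADJ", "ADV", "VERB", "OTHER")

#' Map Universal POS tags to the coarse five-tag set
#'
#' The extraction and polarity rules only test NOUN/ADJ/ADV, so the full
#' Universal tagset is folded to `{NOUN, ADJ, ADV, VERB, OTHER}`. `PROPN`
#' folds to `NOUN` (biomedical taggers often mark clinical terms as proper
#' nouns; the vocabulary filter is the relevance gate), `AUX` to `VERB`.
#'
#' @param pos character vector of POS tags (Universal or already coarse)
#' @return character vector over the coarse set
#' @export
map_upos <- function(pos) {
  pos <- toupper(as.character(pos))
  tab <- c(
    NOUN = "NOUN", PROPN = "NOUN",
    ADJ = "ADJ", ADV = "ADV",
    VERB = "VERB", AUX = "VERB"
  )
  out <- unname(tab[pos])
  out[is.na(out)] <- ifelse(pos[is.na(out)] %in% coarse_pos_set,
                            pos[is.na(out)], "OTHER")
  out
}

#' Tag a sentence through a tagger contract
#'
#' A tagger is any function mapping a sentence string to a
#' [tagged_sentence()] deterministically. This wrapper enforces the
#' contract: indices `0..n-1`, coarse POS, populated deps. A tagger failure
#' is rethrown as a tagging error naming the sentence id.
#'
#' @param sentence character scalar
#' @param tagger a function `(sentence) -> tagged_sentence`
#' @param sentence_id identifier used in the result and in error messages
#' @return a `tagged_sentence`
#' @export
tag_sentence <- function(sentence, tagger, sentence_id = "s1") {
  stopifnot(is.function(tagger))
  ts <- tryCatch(tagger(sentence), error = function(e) {
    stop_aspectrx(
      sprintf("tagging failed for sentence '%s': %s", sentence_id,
              conditionMessage(e)),
      "aspectrx_tagging_error"
    )
  })
  if (!inherits(ts, "tagged_sentence")) {
    stop_aspectrx(
      sprintf("tagger did not return a tagged_sentence for '%s'", sentence_id),
      "aspectrx_tagging_error"
    )
  }
  if (nrow(ts) && !identical(ts$index, seq_len(nrow(ts)) - 1L)) {
    stop_aspectrx(
      sprintf("token indices are not 0..n-1 for sentence '%s'", sentence_id),
      "aspectrx_tagging_error"
    )
  }
  ts$pos <- map_upos(ts$pos)
  attr(ts, "sentence_id") <- sentence_id
  ts
}

# ---- deterministic heuristic tagger -----------------------------------------

heuristic_closed_class <- list(
  det  = c("a", "an", "the", "this", "that", "these", "those", "any", "no",
           "some", "my", "your", "his", "her", "its", "our", "their"),
  prep = c("of", "in", "on", "at", "for", "with", "to", "from", "by", "as",
           "about", "after", "before", "over", "under", "through"),
  pron = c("i", "im", "me", "we", "us", "you", "he", "she", "it", "they",
           "them", "who", "which", "what"),
  conj = c("and", "or", "but", "so", "if", "because", "however", "though",
           "although", "while"),
  aux  = c("is", "am", "are", "was", "were", "be", "been", "being", "have",
           "has", "had", "do", "does", "did", "will", "would", "can",
           "could", "shall", "should", "may", "might", "must", "get",
           "got", "gets")
)

heuristic_adverbs <- c("so", "far", "quite", "very", "truly", "really",
                       "only", "just", "too", "also", "now", "then", "not",
                       "never", "maybe", "perhaps", "again", "still", "much",
                       "more", "less")

heuristic_adjectives <- c("good", "bad", "free", "better", "worse", "best",
                          "worst", "fine", "great", "terrible", "happy",
                          "sad", "black", "huge", "extreme", "positive",
                          "negative")

#' Deterministic heuristic tagger
#'
#' A rule tagger used when no gold tags are registered for a sentence:
#' closed-class word lists plus suffix rules assign coarse POS, and a small
#' positional pass assigns dependency labels (`amod` for an adjective
#' directly before a noun, `compound` for a noun directly before a noun,
#' one `ROOT` on the last plain noun, `dep` otherwise). It is not a parser;
#' it exists so that unknown sentences get stable, repeatable tags.
#' Sentences tagged this way carry attribute `heuristic = TRUE`.
#'
#' @param sentence character scalar (normalized text)
#' @param sentence_id identifier
#' @return a `tagged_sentence`
#' @export
heuristic_tag <- function(sentence, sentence_id = "s1") {
  toks <- strsplit(trimws(sentence), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) {
    out <- tagged_sentence(character(), character(), character(), sentence_id)
    attr(out, "heuristic") <- TRUE
    return(out)
  }
  bare <- gsub("[^a-z0-9']", "", tolower(toks))
  n <- length(toks)
  pos <- character(n)
  for (k in seq_len(n)) {
    w <- bare[k]
    pos[k] <- if (!nzchar(w)) "OTHER"
    else if (w %in% heuristic_adverbs) "ADV"
    else if (w %in% heuristic_adjectives) "ADJ"
    else if (w %in% unlist(heuristic_closed_class[c("det", "prep", "pron",
                                                    "conj")])) "OTHER"
    else if (w %in% heuristic_closed_class$aux) "VERB"
    else if (grepl("ly$", w) && nchar(w) > 3) "ADV"
    else if (grepl("(ive|ful|ous|able|ible|ish|less|al|ic)$", w) &&
             nchar(w) > 4) "ADJ"
    else if (grepl("(ed|ing)$", w) && nchar(w) > 4) "VERB"
    else "NOUN"
  }
  dep <- rep("dep", n)
  nxt <- c(pos[-1], "")
  dep[pos == "ADJ" & nxt == "NOUN"] <- "amod"
  dep[pos == "NOUN" & nxt == "NOUN"] <- "compound"
  plain_noun <- which(pos == "NOUN" & dep == "dep")
  if (length(plain_noun)) dep[plain_noun[length(plain_noun)]] <- "ROOT"
  dep[pos == "OTHER" & bare %in% heuristic_closed_class$det] <- "det"
  out <- tagged_sentence(toks, pos, dep, sentence_id)
  attr(out, "heuristic") <- TRUE
  out
}

# key for gold-tag lookup: letters/apostrophes only, squeezed
sentence_key <- function(x) {
  x <- gsub("[^a-z' ]", " ", tolower(x))
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Gold-tag lookup tagger
#'
#' Builds a [tag_sentence()]-compatible tagger backed by a table of
#' gold-tagged sentences (columns `sentence_id`, `index`, `surface`, `pos`,
#' `dep`). Input sentences are matched on a punctuation-insensitive
#' lowercase key of the stored surfaces; unmatched sentences fall back to
#' the deterministic [heuristic_tag()] and are flagged `heuristic = TRUE`.
#'
#' @param gold optional data.frame of extra gold tags, same columns as the
#'   bundled table (e.g. the `$tags` component of [generate_corpus()])
#' @param bundled logical; include the packaged gold-tag table (the worked
#'   review sentences). Default `TRUE`.
#' @return a tagger function `(sentence) -> tagged_sentence`
#' @export
#' @examples
#' tg <- fixture_tagger()
#' tg("so far im feeling quite positive and free of depressive feelings")
fixture_tagger <- function(gold = NULL, bundled = TRUE) {
  tabs <- list()
  if (bundled) {
    tabs[[1]] <- utils::read.delim(ext_file("gold_tags.tsv"),
                                   stringsAsFactors = FALSE,
                                   comment.char = "#", quote = "")
  }
  if (!is.null(gold)) tabs[[length(tabs) + 1L]] <- as.data.frame(gold)
  lookup <- new.env(parent = emptyenv())
  for (tab in tabs) {
    stopifnot(all(c("sentence_id", "index", "surface", "pos", "dep") %in%
                    names(tab)))
    for (sid in unique(tab$sentence_id)) {
      rows <- tab[tab$sentence_id == sid, , drop = FALSE]
      rows <- rows[order(rows$index), , drop = FALSE]
      ts <- tagged_sentence(rows$surface, rows$pos, rows$dep, sid)
      assign(sentence_key(paste(rows$surface, collapse = " ")), ts,
             envir = lookup)
    }
  }
  function(sentence) {
    key <- sentence_key(sentence)
    if (nzchar(key) && exists(key, envir = lookup, inherits = FALSE)) {
      get(key, envir = lookup, inherits = FALSE)
    } else {
      heuristic_tag(sentence)
    }
  }
}
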