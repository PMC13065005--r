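#' Construct a modifier lexicon
#'
#' Three pairwise-disjoint lowercase word sets driving polarity
#' composition: STRONG intensifiers boost the next opinion word, WEAK
#' modifiers attenuate it, NEGATIVES flip it. Overlap between the sets is
#' rejected at load time so a token's modifier class is always unique.
#'
#' @param strong,weak,negatives character vectors (or paths to one-word-
#'   per-line files when `from_files = TRUE`)
#' @param from_files read the three arguments as file paths
#' @return a `modifier_lexicon`: list of the three lowercase sets
#' @export
modifier_lexicon <- function(strong = character(), weak = character(),
                             negatives = character(), from_files = FALSE) {
  read_set <- function(x) {
    if (from_files) x <- readLines(x, warn = FALSE)
    x <- trimws(tolower(x))
    unique(x[nzchar(x) & !startsWith(x, "#")])
  }
  strong <- read_set(strong)
  weak <- read_set(weak)
  negatives <- read_set(negatives)
  overlap <- c(intersect(strong, weak), intersect(strong, negatives),
               intersect(weak, negatives))
  if (length(overlap)) {
    stop_aspectrx(
      paste0("modifier sets overlap on: ", paste(overlap, collapse = ", ")),
      "aspectrx_config_error"
    )
  }
  structure(list(strong = strong, weak = weak, negatives = negatives),
            class = "modifier_lexicon")
}

#' Bundled modifier lexicon fixture
#'
#' The packaged STRONG/WEAK/NEGATIVES word lists used by the worked
#' examples and the synthetic corpus.
#'
#' @return a `modifier_lexicon`
#' @export
default_modifier_lexicon <- function() {
  modifier_lexicon(ext_file("strong.txt"), ext_file("weak.txt"),
                   ext_file("negatives.txt"), from_files = TRUE)
}

#' Classify a token against the modifier lexicon
#'
#' Membership is tested on the lowercase surface; disjointness of the sets
#' makes the answer unique.
#'
#' @param token a token surface string (or one row of a tagged sentence)
#' @param modlex a [modifier_lexicon()]
#' @return one of `"none"`, `"strong"`, `"weak"`, `"negative"`
#' @export
modifier_class <- function(token, modlex) {
  if (is.data.frame(token)) token <- token$surface
  w <- tolower(token)
  if (w %in% modlex$strong) "strong"
  else if (w %in% modlex$weak) "weak"
  else if (w %in% modlex$negatives) "negative"
  else "none"
}

#' Load a SentiWordNet-style sentiment lexicon
#'
#' Tab-separated file with columns `term`, `pos` (coarse POS tag), `pos_score`,
#' `neg_score`, `obj_score`; `#` comment lines allowed. Each triple must be
#' non-negative and sum to 1 (within 1e-9). Lookup is exact on
#' (lowercase term, coarse POS).
#'
#' @param path TSV path; default is the bundled first-sense fixture lexicon
#' @return a `sentiment_lexicon`: environment-backed map plus the source
#'   table in `$table`
#' @export
sentiment_lexicon <- function(path = ext_file("sentiment_lexicon.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
  need <- c("term", "pos", "pos_score", "neg_score", "obj_score")
  if (!all(need %in% names(tab))) {
    stop_aspectrx(
      paste0("sentiment lexicon needs columns: ", paste(need, collapse = ", ")),
      "aspectrx_format_error"
    )
  }
  tot <- tab$pos_score + tab$neg_score + tab$obj_score
  if (any(abs(tot - 1) > 1e-9) ||
      any(tab$pos_score < 0 | tab$neg_score < 0 | tab$obj_score < 0)) {
    stop_aspectrx("sentiment triples must be non-negative and sum to 1",
                  "aspectrx_format_error")
  }
  map <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(tab))) {
    assign(paste(tolower(tab$term[k]), map_upos(tab$pos[k]), sep = "\r"),
           c(pos = tab$pos_score[k], neg = tab$neg_score[k],
             obj = tab$obj_score[k]),
           envir = map)
  }
  structure(list(map = map, table = tab), class = "sentiment_lexicon")
}

#' Build a sentiment lexicon from vectors
#'
#' @param term,pos character vectors; `pos_score`, `neg_score`, `obj_score`
#'   numeric, summing to 1 per row
#' @param pos_score,neg_score,obj_score numeric vectors
#' @return a `sentiment_lexicon`
#' @export
sentiment_lexicon_from <- function(term, pos, pos_score, neg_score,
                                   obj_score) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(
    data.frame(term = term, pos = pos, pos_score = pos_score,
               neg_score = neg_score, obj_score = obj_score),
    tmp, sep = "\t", row.names = FALSE, quote = FALSE
  )
  sentiment_lexicon(tmp)
}

#' Look up a token's opinion triple
#'
#' Opinion words are restricted to the configured POS set (default
#' adjectives and adverbs); verbs like "experienced" therefore miss even
#' when the surface is in the lexicon, matching the treatment of neutral
#' non-opinion words in the composition rules.
#'
#' @param surface token surface string
#' @param pos coarse POS tag of the token
#' @param lexicon a [sentiment_lexicon()]
#' @param opinion_pos POS tags eligible to carry opinion
#' @return named numeric `c(pos=, neg=, obj=)`, or `NULL` on a miss
#' @export
lookup_opinion <- function(surface, pos, lexicon,
                           opinion_pos = c("ADJ", "ADV")) {
  pos <- map_upos(pos)
  if (!(pos %in% opinion_pos)) return(NULL)
  key <- paste(tolower(surface), pos, sep = "\r")
  if (exists(key, envir = lexicon$map, inherits = FALSE)) {
    get(key, envir = lexicon$map, inherits = FALSE)
  } else {
    NULL
  }
}
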