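#' Normalize raw review text
#'
#' Lowercases the text, strips leading digit runs from tokens (so dose
#' numbers like `"300"` and the numeric prefix of `"2x"` disappear while
#' alphanumerics such as `"b12"` survive), collapses whitespace runs to a
#' single space and trims the ends. Optionally removes stopwords, always
#' exempting any word found in the modifier lexicons so that negators and
#' intensifiers needed by polarity scoring are never discarded.
#'
#' Stopword removal is OFF by default: the downstream polarity rules depend
#' on function words such as "not", "quite" and "truly", and the worked
#' review sentences the pipeline is validated on retain them.
#'
#' @param raw character scalar (any string; `""` yields `""`)
#' @param remove_stopwords logical; default `FALSE`
#' @param stopwords character vector of stopwords; default is the bundled
#'   English list
#' @param keep character vector of words exempt from stopword removal
#'   (typically `unlist(modifier_lexicon())`); matched after lowercasing
#' @return normalized character scalar
#' @export
#' @examples
#' normalize_text("This Medicine  is terrible")
#' normalize_text("300 mg 2x a day")
normalize_text <- function(raw, remove_stopwords = FALSE,
                           stopwords = NULL, keep = character()) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw)) return("")
  x <- tolower(raw)
  toks <- strsplit(x, "[[:space:]]+")[[1]]
  toks <- sub("^[0-9]+", "", toks)
  toks <- toks[nzchar(toks)]
  if (remove_stopwords && length(toks)) {
    if (is.null(stopwords)) stopwords <- default_stopwords()
    bare <- gsub("[^a-z']", "", toks)
    drop <- bare %in% setdiff(tolower(stopwords), tolower(keep))
    toks <- toks[!drop]
  }
  paste(toks, collapse = " ")
}

#' Bundled English stopword list
#'
#' @return character vector of lowercase stopwords
#' @export
default_stopwords <- function() {
  readLines(ext_file("stopwords_en.txt"), warn = FALSE)
}

#' Segment normalized text into sentences
#'
#' Splits on terminal punctuation (`.`, `!`, `?`) followed by whitespace or
#' end of string; the punctuation stays attached to its sentence.
#' Abbreviations are not special-cased (drug reviews are informal prose).
#' Never returns empty strings.
#'
#' @param text character scalar of normalized text
#' @return character vector of sentences (length 0 for empty input)
#' @export
#' @examples
#' split_sentences("it works. i feel fine.")
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  parts <- strsplit(text, "(?<=[.!?])[[:space:]]+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}
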