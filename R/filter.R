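#' Load a condition-specific medical vocabulary
#'
#' Reads a plain-text word list (UTF-8, one term per line, `#` comments and
#' blank lines ignored), lowercases and normalizes each term with
#' [normalize_text()] (stopword removal off) and deduplicates.
#'
#' @param source path to the term-list file, or a character vector of terms
#' @param condition condition name the vocabulary describes
#' @return a `medical_vocabulary`: list with `condition` and `terms`
#'   (character vector, lowercase, unique)
#' @export
load_vocabulary <- function(source, condition = "unknown") {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE, encoding = "UTF-8")
  } else {
    as.character(source)
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  terms <- unique(vapply(lines, normalize_text, character(1),
                         USE.NAMES = FALSE))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) {
    stop_aspectrx("vocabulary source contains no terms",
                  "aspectrx_config_error")
  }
  structure(list(condition = condition, terms = terms),
            class = "medical_vocabulary")
}

#' Construct a vocabulary from an in-memory term vector
#'
#' @param terms character vector of terms
#' @param condition condition name
#' @return a `medical_vocabulary`
#' @export
medical_vocabulary <- function(terms, condition = "unknown") {
  load_vocabulary(terms, condition)
}

#' Filter aspect candidates by vocabulary similarity
#'
#' Scores every candidate with [term_similarity()] and keeps those at or
#' above the threshold (the cutoff is inclusive). Order is preserved;
#' dropped candidates get a reason code (`below_threshold` or
#' `oov_zero_vector` when the embedding was the zero sentinel).
#'
#' @param candidates data.frame from [extract_candidates()]
#' @param vocab a [medical_vocabulary()]
#' @param embedder an embedder
#' @param threshold similarity cutoff in `[0, 1]`; default 0.7
#' @return the candidate data.frame with added columns `score`, `kept`,
#'   `reason` (`""` for kept rows)
#' @export
filter_candidates <- function(candidates, vocab, embedder, threshold = 0.7) {
  stopifnot(threshold >= 0, threshold <= 1)
  n <- nrow(candidates)
  score <- numeric(n)
  oov <- logical(n)
  for (k in seq_len(n)) {
    v <- embed_term(candidates$surface[k], embedder)
    oov[k] <- sqrt(sum(v^2)) == 0
    score[k] <- term_similarity(candidates$surface[k], vocab, embedder)
  }
  kept <- score >= threshold
  reason <- ifelse(kept, "",
                   ifelse(oov, "oov_zero_vector", "below_threshold"))
  out <- candidates
  out$score <- score
  out$kept <- kept
  out$reason <- reason
  out
}
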