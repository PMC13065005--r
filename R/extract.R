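#' Extract aspect-term candidates from a tagged sentence
#'
#' A single left-to-right pass over the tokens applies three patterns:
#'
#' * `single_noun` — a NOUN whose dependency is `ROOT` or `nmod`, emitted
#'   when no compound prefix is pending;
#' * `compound_pair` — a NOUN tagged `compound` is stored as a prefix and
#'   the pair is emitted when the following token closes it;
#' * `adj_licensed` — an `amod` ADJ raises a flag and the next NOUN is
#'   emitted (the noun alone, not the adjective).
#'
#' Two dialects are provided. `"as_printed"` follows the pseudocode of the
#' rule scheme to the letter: the two if/else-if chains run independently
#' per token (one token can be emitted twice), the pending compound prefix
#' is closed by the next token of *any* part of speech, the `comp` marker
#' is never cleared, and adjective licensing has no distance limit.
#' `"strict"` is the production dialect: the compound pair only closes on a
#' NOUN (a pending prefix is dropped otherwise), prefix and marker are
#' cleared together, the licensed noun must lie within 3 tokens of its
#' adjective, and duplicate candidates over the same token indices are
#' merged (first rule wins). Surfaces are capped at two tokens in both
#' dialects.
#'
#' @param sentence a [tagged_sentence()]
#' @param mode `"strict"` (default) or `"as_printed"`
#' @return data.frame with columns `surface`, `rule`, `idx1`, `idx2`
#'   (`idx2` is `NA` for one-token candidates), in emission order
#' @export
#' @examples
#' ts <- tagged_sentence(c("depressive", "feelings"), c("ADJ", "NOUN"),
#'                       c("amod", "ROOT"))
#' extract_candidates(ts)
extract_candidates <- function(sentence, mode = c("strict", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sentence, "tagged_sentence"))
  n <- nrow(sentence)
  out_surface <- character()
  out_rule <- character()
  out_i1 <- integer()
  out_i2 <- integer()
  emit <- function(surface, rule, i1, i2 = NA_integer_) {
    out_surface[length(out_surface) + 1L] <<- surface
    out_rule[length(out_rule) + 1L] <<- rule
    out_i1[length(out_i1) + 1L] <<- i1
    out_i2[length(out_i2) + 1L] <<- i2
  }

  prepend <- ""        # surface of a pending compound prefix
  prepend_idx <- NA_integer_
  comp_tag <- ""       # "comp" once a prefix has been stored
  flag <- 0L           # 1 after an amod ADJ
  flag_pos <- NA_integer_

  for (k in seq_len(n)) {
    surf <- sentence$surface[k]
    pos <- sentence$pos[k]
    dep <- sentence$dep[k]
    idx <- sentence$index[k]

    # chain 1: nouns, compounds
    if (pos == "NOUN" && !nzchar(prepend) && dep %in% c("ROOT", "nmod")) {
      emit(surf, "single_noun", idx)
    } else if (pos == "NOUN" && dep == "compound") {
      prepend <- surf
      prepend_idx <- idx
      comp_tag <- "comp"
    } else if (nzchar(prepend) && comp_tag == "comp") {
      if (mode == "as_printed" || pos == "NOUN") {
        emit(paste(prepend, surf), "compound_pair", prepend_idx, idx)
      }
      prepend <- ""
      prepend_idx <- NA_integer_
      if (mode == "strict") comp_tag <- ""
    }

    # chain 2: adjective-licensed nouns (independent of chain 1)
    if (pos == "ADJ" && dep == "amod") {
      flag <- 1L
      flag_pos <- idx
    } else if (pos == "NOUN" && flag == 1L) {
      if (mode == "as_printed" || (idx - flag_pos) <= 3L) {
        emit(surf, "adj_licensed", idx)
      }
      flag <- 0L
      flag_pos <- NA_integer_
    }
  }

  res <- data.frame(surface = out_surface, rule = out_rule,
                    idx1 = out_i1, idx2 = out_i2,
                    stringsAsFactors = FALSE)
  if (mode == "strict" && nrow(res) > 1L) {
    key <- paste(res$idx1, res$idx2)
    res <- res[!duplicated(key), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Token indices covered by a candidate set
#'
#' @param candidates a candidate data.frame from [extract_candidates()]
#' @return sorted unique integer vector of 0-based token indices
#' @export
candidate_indices <- function(candidates) {
  sort(unique(c(candidates$idx1, candidates$idx2[!is.na(candidates$idx2)])))
}
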