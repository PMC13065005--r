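#' Classification thresholds
#'
#' Bundles the three cutoffs the polarity stage uses: the objectivity gate
#' `theta_obj` (opinion words whose objective score reaches the gate carry
#' no sentiment), and the class band edges `theta_pos` / `theta_neg` that
#' partition the polarity scale: scores above `theta_pos` are positive,
#' below `theta_neg` negative, the closed band between them neutral.
#' Requires `0 <= theta_neg < theta_pos <= 1`.
#'
#' @param theta_obj objectivity gate in `[0, 1]`; default 0.5
#' @param theta_pos upper band edge; default 0.6
#' @param theta_neg lower band edge; default 0.4
#' @param sim_threshold vocabulary-similarity cutoff carried alongside for
#'   the pipeline; default 0.7
#' @return a `thresholds` list
#' @export
thresholds <- function(theta_obj = 0.5, theta_pos = 0.6, theta_neg = 0.4,
                       sim_threshold = 0.7) {
  stopifnot(theta_obj >= 0, theta_obj <= 1,
            theta_neg >= 0, theta_pos <= 1, theta_neg < theta_pos,
            sim_threshold >= 0, sim_threshold <= 1)
  structure(list(theta_obj = theta_obj, theta_pos = theta_pos,
                 theta_neg = theta_neg, sim_threshold = sim_threshold),
            class = "thresholds")
}

#' Apply a pending modifier flag to a polarity value
#'
#' Composition rules on the unit interval, keyed by the flag set by the
#' last modifier word and by whether the opinion word scored on its
#' positive side (`pos_indicator = 1`) or negative side (`0`):
#'
#' * boost (`flag 1` with a positive word, or `flag 2` with a negative
#'   word): `1 - (1 - p)^2`;
#' * cross case (`flag 1` with a negative word, or `flag 2` with a
#'   positive word): in `"as_printed"` dialect the literal rule
#'   `1 - (1 - p)` — the identity; in `"calibrated"` dialect the
#'   attenuation `p^2`;
#' * negation (`flag 3`): `1 - p`, an involution;
#' * `flag 0`: unchanged.
#'
#' For `p` in `[0, 1]`, `1 - (1 - p)^2 >= p >= p^2`, so boosted >=
#' unmodified >= attenuated, and every rule maps the unit interval to
#' itself.
#'
#' @param p polarity in `[0, 1]`
#' @param flag integer in `{0, 1, 2, 3}`
#' @param pos_indicator 0 or 1
#' @param mode `"calibrated"` (default) or `"as_printed"`
#' @return numeric in `[0, 1]`
#' @export
#' @examples
#' apply_modifier(0.7, 1, 1)              # 0.91
#' apply_modifier(0.7, 2, 1)              # 0.49
#' apply_modifier(0.2, 3, 1)              # 0.8
apply_modifier <- function(p, flag, pos_indicator,
                           mode = c("calibrated", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(p >= 0, p <= 1, pos_indicator %in% c(0, 1))
  if (!(flag %in% 0:3)) {
    stop_aspectrx("modifier flag must be in {0,1,2,3}",
                  "aspectrx_contract_error")
  }
  if ((flag == 1 && pos_indicator == 1) || (flag == 2 && pos_indicator == 0)) {
    1 - (1 - p)^2
  } else if ((flag == 1 && pos_indicator == 0) ||
             (flag == 2 && pos_indicator == 1)) {
    if (mode == "as_printed") 1 - (1 - p) else p^2
  } else if (flag == 3) {
    1 - p
  } else {
    p
  }
}

#' Detect sentence polarity
#'
#' A single left-to-right pass over the tokens. Aspect tokens are skipped;
#' a modifier word sets the flag (1 strong, 2 weak, 3 negation); an opinion
#' word (lexicon hit on an eligible POS) whose objective score is below the
#' gate sets the running polarity and then consumes the flag through
#' [apply_modifier()]. The last-scored opinion word wins (the running value
#' is overwritten, not averaged).
#'
#' Dialects: `"as_printed"` follows the composition pseudocode literally —
#' a positive-side opinion word clamps the base polarity to 1 before
#' modification, and the flag persists across opinion words. `"calibrated"`
#' (default) takes the raw lexicon magnitude as the base (`pos`, or
#' `1 - neg` on the negative side) and resets the flag after each scored
#' opinion word, so a modifier scopes to the next opinion word only.
#'
#' @param sentence a [tagged_sentence()]
#' @param aspect_indices integer vector of 0-based token indices belonging
#'   to kept aspect terms (skipped during scoring)
#' @param modlex a [modifier_lexicon()]
#' @param sentlex a [sentiment_lexicon()]
#' @param th a [thresholds()]
#' @param mode `"calibrated"` (default) or `"as_printed"`
#' @param opinion_pos POS tags eligible to carry opinion
#' @return a `polarity_state`: list with `polarity` in `[0, 1]`, final
#'   `flag`, and `opinion_seen` (whether any opinion word scored)
#' @export
detect_polarity <- function(sentence, aspect_indices, modlex, sentlex,
                            th = thresholds(),
                            mode = c("calibrated", "as_printed"),
                            opinion_pos = c("ADJ", "ADV")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sentence, "tagged_sentence"))
  aspect_indices <- as.integer(aspect_indices)
  stopifnot(all(aspect_indices %in% sentence$index))
  flag <- 0L
  polarity <- 0
  opinion_seen <- FALSE

  for (k in seq_len(nrow(sentence))) {
    idx <- sentence$index[k]
    if (idx %in% aspect_indices) next
    mc <- modifier_class(sentence$surface[k], modlex)
    if (mc != "none") {
      flag <- switch(mc, strong = 1L, weak = 2L, negative = 3L)
      next
    }
    triple <- lookup_opinion(sentence$surface[k], sentence$pos[k], sentlex,
                             opinion_pos = opinion_pos)
    if (is.null(triple)) next
    if (triple[["obj"]] >= th$theta_obj) next
    if (triple[["pos"]] >= triple[["neg"]]) {
      pos_indicator <- 1
      polarity <- if (mode == "as_printed") 1 else triple[["pos"]]
    } else {
      pos_indicator <- 0
      polarity <- 1 - triple[["neg"]]
    }
    polarity <- apply_modifier(polarity, flag, pos_indicator, mode = mode)
    opinion_seen <- TRUE
    if (mode == "calibrated") flag <- 0L
  }

  structure(list(polarity = polarity, flag = flag,
                 opinion_seen = opinion_seen),
            class = "polarity_state")
}

#' Classify a polarity state into a sentiment label
#'
#' When no opinion word scored, the sentinel `"no_opinion"` is returned
#' regardless of the numeric value (a zero score from silence is not a
#' negative judgement). Otherwise scores above `theta_pos` are
#' `"positive"`, below `theta_neg` `"negative"`, and the closed band
#' between them `"neutral"` — exactly one label for every score.
#'
#' @param state a `polarity_state` from [detect_polarity()], or a bare
#'   numeric polarity (then `opinion_seen = TRUE` is assumed)
#' @param th a [thresholds()]
#' @return one of `"positive"`, `"neutral"`, `"negative"`, `"no_opinion"`
#' @export
classify_label <- function(state, th = thresholds()) {
  if (is.numeric(state)) {
    state <- list(polarity = state, opinion_seen = TRUE)
  }
  if (!isTRUE(state$opinion_seen)) return("no_opinion")
  p <- state$polarity
  if (p > th$theta_pos) "positive"
  else if (p < th$theta_neg) "negative"
  else "neutral"
}

sentiment_labels <- c("positive", "neutral", "negative", "no_opinion")
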