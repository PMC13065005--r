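#' Token-overlap precision, recall and F1
#'
#' Tokens are compared as lowercase surface strings with set semantics:
#' `correct = |actual intersect predicted|`, precision `correct/|predicted|`,
#' recall `correct/|actual|`, `F1 = 2PR/(P+R)`. An empty predicted set gives
#' precision 0, an empty actual set recall 0, and F1 is 0 whenever
#' `P + R = 0` (conventions over undefined ratios; flagged via warning when
#' a denominator is empty).
#'
#' @param actual character vector of gold tokens
#' @param predicted character vector of predicted tokens
#' @return list with `precision`, `recall`, `f1` and the `counts`
#'   (`correct`, `predicted`, `actual`)
#' @export
#' @examples
#' token_prf(c("a", "b", "c", "d"), c("a", "b", "e"))
token_prf <- function(actual, predicted) {
  a <- unique(tolower(trimws(actual)))
  a <- a[nzchar(a)]
  p <- unique(tolower(trimws(predicted)))
  p <- p[nzchar(p)]
  correct <- length(intersect(a, p))
  if (!length(p) || !length(a)) {
    warning("token_prf: empty ", if (!length(p)) "predicted" else "actual",
            " set; zero-denominator convention applied", call. = FALSE)
  }
  prec <- if (length(p)) correct / length(p) else 0
  rec <- if (length(a)) correct / length(a) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       counts = c(correct = correct, predicted = length(p),
                  actual = length(a)))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two aligned label sequences:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` the fraction
#' of equal positions and expected agreement `pe` the inner product of the
#' two raters' marginal label distributions. When both raters use a single
#' identical label throughout (`pe = 1`), agreement is perfect and kappa is
#' defined as 1.
#'
#' @param labels_a,labels_b equal-length vectors of categorical labels
#' @return list with `kappa`, `observed_agreement`, `expected_agreement`
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b) || !length(labels_a)) {
    stop_aspectrx("label sequences must be non-empty and equal length",
                  "aspectrx_contract_error")
  }
  n <- length(labels_a)
  po <- mean(labels_a == labels_b)
  cats <- union(labels_a, labels_b)
  pa <- vapply(cats, function(c) mean(labels_a == c), numeric(1))
  pb <- vapply(cats, function(c) mean(labels_b == c), numeric(1))
  pe <- sum(pa * pb)
  kappa <- if (pe >= 1 - 1e-12) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, observed_agreement = po, expected_agreement = pe)
}

#' Fleiss' kappa for a rating matrix
#'
#' @param matrix items x categories matrix of rater counts; every row must
#'   sum to the same number of raters (>= 2), over >= 2 items
#' @return list with `kappa`, `observed_agreement` (mean per-item
#'   agreement), `expected_agreement`
#' @export
fleiss_kappa <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2) {
    stop_aspectrx("need at least 2 items", "aspectrx_contract_error")
  }
  n_raters <- sum(m[1, ])
  if (n_raters < 2 || any(rowSums(m) != n_raters)) {
    stop_aspectrx("every row must sum to the same rater count (>= 2)",
                  "aspectrx_contract_error")
  }
  N <- nrow(m)
  p_i <- (rowSums(m^2) - n_raters) / (n_raters * (n_raters - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / (N * n_raters)
  pe <- sum(p_j^2)
  kappa <- if (pe >= 1 - 1e-12) 1 else (p_bar - pe) / (1 - pe)
  list(kappa = kappa, observed_agreement = p_bar, expected_agreement = pe)
}

#' Majority-vote consensus label
#'
#' Strict majority wins; without one the sentinel `"unresolved"` is
#' returned so ties go to human adjudication rather than a silent default.
#'
#' @param labels vector of per-annotator labels
#' @param n_annotators expected number of labels
#' @return the consensus label, or `"unresolved"`
#' @export
majority_vote <- function(labels, n_annotators = length(labels)) {
  labels <- as.character(labels)
  if (length(labels) != n_annotators) {
    stop_aspectrx("label count does not match n_annotators",
                  "aspectrx_contract_error")
  }
  tab <- sort(table(labels), decreasing = TRUE)
  if (tab[1] * 2 > length(labels)) names(tab)[1] else "unresolved"
}

#' Token classes for sequence evaluation
#'
#' Labels every token of a sentence as `non_aspect`, `uni_word` (part of a
#' one-token aspect) or `bi_word` (part of a two-token aspect); a token
#' covered by both resolves to `bi_word`.
#'
#' @param sentence a [tagged_sentence()]
#' @param aspects candidate data.frame (columns `idx1`, `idx2`)
#' @return character vector, one class per token
#' @export
token_classes <- function(sentence, aspects) {
  stopifnot(inherits(sentence, "tagged_sentence"))
  cls <- rep("non_aspect", nrow(sentence))
  if (!nrow(sentence)) return(cls)
  pos_of <- function(idx) match(idx, sentence$index)
  for (k in seq_len(nrow(aspects))) {
    i1 <- aspects$idx1[k]; i2 <- aspects$idx2[k]
    if (!is.na(i2)) {
      if (is.na(pos_of(i1)) || is.na(pos_of(i2))) {
        stop_aspectrx("aspect index out of bounds", "aspectrx_contract_error")
      }
      cls[pos_of(i1)] <- "bi_word"
      cls[pos_of(i2)] <- "bi_word"
    } else {
      if (is.na(pos_of(i1))) {
        stop_aspectrx("aspect index out of bounds", "aspectrx_contract_error")
      }
      if (cls[pos_of(i1)] != "bi_word") cls[pos_of(i1)] <- "uni_word"
    }
  }
  cls
}

#' Per-class precision / recall / F1 report
#'
#' One-vs-rest PRF per class over two aligned label sequences, mirroring a
#' per-class token evaluation table. Classes absent from both sequences but
#' requested via `classes` come back as zero rows with a warning.
#'
#' @param gold,predicted equal-length label vectors
#' @param classes classes to report; default the union of observed labels
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support` (gold count); attribute `micro` carries pooled counts
#' @export
per_class_report <- function(gold, predicted, classes = NULL) {
  gold <- as.character(gold)
  predicted <- as.character(predicted)
  if (length(gold) != length(predicted)) {
    stop_aspectrx("gold and predicted must align", "aspectrx_contract_error")
  }
  if (is.null(classes)) classes <- sort(union(gold, predicted))
  rows <- lapply(classes, function(cl) {
    tp <- sum(gold == cl & predicted == cl)
    np <- sum(predicted == cl)
    na_ <- sum(gold == cl)
    if (np == 0 && na_ == 0) {
      warning("class '", cl, "' absent from gold and predicted; zero row",
              call. = FALSE)
    }
    prec <- if (np) tp / np else 0
    rec <- if (na_) tp / na_ else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = na_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "micro") <- c(correct = sum(gold == predicted),
                          total = length(gold))
  out
}
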