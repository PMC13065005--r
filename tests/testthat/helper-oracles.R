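# Independent line-by-line transcriptions of the two rule pseudocodes, plus
# brute-force statistics oracles. These deliberately share no code with the
# package implementation: plain loops over plain data.frames.

# --- extraction oracle (literal pseudocode, lines 1-22) ----------------------
oracle_extract <- function(df) {
  FLAG <- 0
  PREPEND <- ""
  TAG <- ""
  AspectTerms <- character()
  for (k in seq_len(nrow(df))) {
    token <- df$surface[k]
    if (df$pos[k] == "NOUN" && PREPEND == "" &&
        (df$dep[k] == "ROOT" || df$dep[k] == "nmod")) {
      AspectTerms <- c(AspectTerms, token)
    } else if (df$pos[k] == "NOUN" && df$dep[k] == "compound") {
      PREPEND <- token
      TAG <- "comp"
    } else if (PREPEND != "" && TAG == "comp") {
      AspectTerms <- c(AspectTerms, paste(PREPEND, token))
      PREPEND <- ""
    }
    if (df$pos[k] == "ADJ" && df$dep[k] == "amod") {
      FLAG <- 1
    } else if (df$pos[k] == "NOUN" && FLAG == 1) {
      AspectTerms <- c(AspectTerms, token)
      FLAG <- 0
    }
  }
  AspectTerms
}

# --- polarity oracle (literal pseudocode, with Theta gate) -------------------
# sentdf: data.frame(term, pos, pos_score, neg_score, obj_score)
# modifier sets are plain character vectors; aspect is a set of 0-based indices
oracle_polarity <- function(df, aspect, strong, weak, negatives, sentdf,
                            theta, opinion_pos = c("ADJ", "ADV")) {
  FLAG <- 0
  polarity <- 0
  for (k in seq_len(nrow(df))) {
    if ((k - 1L) %in% aspect) next
    tokenl <- tolower(df$surface[k])
    if (tokenl %in% c(strong, weak, negatives)) {
      if (tokenl %in% strong) FLAG <- 1
      else if (tokenl %in% weak) FLAG <- 2
      else if (tokenl %in% negatives) FLAG <- 3
    } else {
      hit <- which(sentdf$term == tokenl & sentdf$pos == df$pos[k])
      if (length(hit) && df$pos[k] %in% opinion_pos) {
        pos_s <- sentdf$pos_score[hit[1]]
        neg_s <- sentdf$neg_score[hit[1]]
        obj_s <- sentdf$obj_score[hit[1]]
        if (obj_s >= theta) next
        if (pos_s >= neg_s) {
          posI <- 1
          polarity <- 1
        } else {
          posI <- 0
          polarity <- 1 - neg_s
        }
        if ((FLAG == 1 && posI == 1) || (FLAG == 2 && posI == 0)) {
          polarity <- 1 - (1 - polarity)^2
        } else if ((FLAG == 1 && posI == 0) || (FLAG == 2 && posI == 1)) {
          polarity <- 1 - (1 - polarity)
        } else if (FLAG == 3 && (posI == 0 || posI == 1)) {
          polarity <- 1 - polarity
        }
      }
    }
  }
  polarity
}

# --- agreement / PRF oracles -------------------------------------------------
oracle_cohen <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  n <- length(a)
  tab <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_len(n)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - 1e-12) 1 else (po - pe) / (1 - pe)
}

oracle_fleiss <- function(m) {
  N <- nrow(m)
  n <- sum(m[1, ])
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(ncol(m))) s <- s + m[i, j] * (m[i, j] - 1)
    P_i[i] <- s / (n * (n - 1))
  }
  p_j <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) p_j[j] <- sum(m[, j]) / (N * n)
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (Pe >= 1 - 1e-12) 1 else (Pbar - Pe) / (1 - Pe)
}

oracle_per_class <- function(gold, pred, cl) {
  tp <- fp <- fn <- 0
  for (i in seq_along(gold)) {
    if (pred[i] == cl && gold[i] == cl) tp <- tp + 1
    if (pred[i] == cl && gold[i] != cl) fp <- fp + 1
    if (pred[i] != cl && gold[i] == cl) fn <- fn + 1
  }
  p <- if (tp + fp) tp / (tp + fp) else 0
  r <- if (tp + fn) tp / (tp + fn) else 0
  f <- if (p + r) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# --- random-case generators --------------------------------------------------
# random tagged sentences over a small surface pool; modifiers/opinion words
# are drawn from dedicated sub-pools so lexicon membership is controllable
rand_sentence_pool <- list(
  plain = sprintf("t%02d", 1:12),
  strong = c("ms1", "ms2"),
  weak = c("mw1", "mw2"),
  neg = c("mn1", "mn2"),
  opinion = sprintf("op%d", 1:6)
)

rand_tagged <- function(max_len = 12) {
  len <- sample(1:max_len, 1)
  pool <- unlist(rand_sentence_pool, use.names = FALSE)
  data.frame(
    surface = sample(pool, len, replace = TRUE),
    pos = sample(c("NOUN", "ADJ", "ADV", "VERB", "OTHER"), len,
                 replace = TRUE),
    dep = sample(c("ROOT", "nmod", "compound", "amod", "dobj", "det", "dep"),
                 len, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# random sentiment table over the opinion pool, triples normalized to sum 1
rand_sent_table <- function() {
  k <- length(rand_sentence_pool$opinion)
  pos_tags <- sample(c("ADJ", "ADV"), k, replace = TRUE)
  raw <- matrix(stats::runif(3 * k), ncol = 3)
  raw <- raw / rowSums(raw)
  data.frame(term = rand_sentence_pool$opinion, pos = pos_tags,
             pos_score = raw[, 1], neg_score = raw[, 2], obj_score = raw[, 3],
             stringsAsFactors = FALSE)
}

as_ts <- function(df, id = "s") {
  aspectrx::tagged_sentence(df$surface, df$pos, df$dep, id)
}
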