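test_that("opinion lookup is exact on (surface, POS) with a POS gate", {
  lex <- sentiment_lexicon_from(
    term = c("lucky", "experienced"),
    pos = c("ADJ", "VERB"),
    pos_score = c(0.7, 0.5), neg_score = c(0, 0.2), obj_score = c(0.3, 0.3)
  )
  expect_equal(unname(lookup_opinion("lucky", "ADJ", lex)), c(0.7, 0, 0.3))
  # verbs are outside the default opinion POS set even when present
  expect_null(lookup_opinion("experienced", "VERB", lex))
  expect_null(lookup_opinion("absent", "ADJ", lex))
})

test_that("modifier classes come from disjoint lowercase sets", {
  ml <- modifier_lexicon(strong = "truly", weak = "quite", negatives = "not")
  expect_identical(modifier_class("truly", ml), "strong")
  expect_identical(modifier_class("Quite", ml), "weak")
  expect_identical(modifier_class("not", ml), "negative")
  expect_identical(modifier_class("table", ml), "none")
  expect_error(modifier_lexicon(strong = "very", weak = "very"),
               class = "aspectrx_config_error")
})

test_that("modifier composition rules and their edge cases", {
  expect_equal(apply_modifier(0.7, 1, 1), 0.91)
  expect_equal(apply_modifier(0.7, 2, 1, mode = "calibrated"), 0.49)
  expect_equal(apply_modifier(0.7, 2, 1, mode = "as_printed"), 0.7)
  expect_equal(apply_modifier(0.2, 3, 1), 0.8)
  expect_equal(apply_modifier(apply_modifier(0.2, 3, 1), 3, 1), 0.2)
  expect_equal(apply_modifier(0.3, 0, 0), 0.3)
  expect_error(apply_modifier(0.5, 5, 1), class = "aspectrx_contract_error")
})

test_that("boost/identity/attenuation ordering and range over random triples", {
  set.seed(19)
  for (i in 1:10000) {
    p <- runif(1)
    flag <- sample(0:3, 1)
    posI <- sample(0:1, 1)
    mode <- sample(c("calibrated", "as_printed"), 1)
    out <- apply_modifier(p, flag, posI, mode)
    expect_gte(out, 0)
    expect_lte(out, 1)
  }
  for (p in runif(200)) {
    expect_gte(1 - (1 - p)^2, p)
    expect_gte(p, p^2)
    expect_equal(apply_modifier(apply_modifier(p, 3, 0), 3, 0), p,
                 tolerance = 1e-12)
  }
})

test_that("worked sentences score as expected in calibrated mode", {
  act <- tag_sentence(actemra_text, fx_tagger, "act")
  st <- detect_polarity(act, c(11L, 12L), fx_modlex, fx_sentlex, fx_th)
  expect_equal(st$polarity, 0.91)
  expect_true(st$opinion_seen)
  expect_identical(classify_label(st, fx_th), "positive")

  r1 <- tag_sentence(r1_text, fx_tagger, "r1")
  st <- detect_polarity(r1, 10L, fx_modlex, fx_sentlex, fx_th)
  expect_equal(st$polarity, 0.49)
  expect_identical(classify_label(st, fx_th), "neutral")

  quiet <- tagged_sentence(c("i", "took", "it", "yesterday"),
                           c("OTHER", "VERB", "OTHER", "OTHER"),
                           c("nsubj", "ROOT", "dobj", "npadvmod"))
  st <- detect_polarity(quiet, integer(), fx_modlex, fx_sentlex, fx_th)
  expect_equal(st$polarity, 0)
  expect_false(st$opinion_seen)
  expect_identical(classify_label(st, fx_th), "no_opinion")
})

test_that("objectivity gate silences high-obj opinion words", {
  ts <- tagged_sentence(c("it", "is", "huge"), c("OTHER", "VERB", "ADJ"),
                        c("nsubj", "ROOT", "acomp"))
  st <- detect_polarity(ts, integer(), fx_modlex, fx_sentlex, fx_th)
  expect_false(st$opinion_seen)
  expect_identical(classify_label(st, fx_th), "no_opinion")
})

test_that("printed dialect matches the literal pseudocode oracle on 1000 random cases", {
  set.seed(11)
  th <- thresholds()
  for (i in 1:1000) {
    df <- rand_tagged(12)
    sentdf <- rand_sent_table()
    k_asp <- sample(0:min(3, nrow(df)), 1)
    aspect <- sample(seq_len(nrow(df)), size = k_asp) - 1L
    ml <- modifier_lexicon(strong = rand_sentence_pool$strong,
                           weak = rand_sentence_pool$weak,
                           negatives = rand_sentence_pool$neg)
    sl <- sentiment_lexicon_from(sentdf$term, sentdf$pos, sentdf$pos_score,
                                 sentdf$neg_score, sentdf$obj_score)
    got <- detect_polarity(as_ts(df), aspect, ml, sl, th,
                           mode = "as_printed")
    want <- oracle_polarity(df, aspect, rand_sentence_pool$strong,
                            rand_sentence_pool$weak, rand_sentence_pool$neg,
                            sentdf, th$theta_obj)
    expect_equal(got$polarity, want, tolerance = 1e-12)
  }
})

test_that("polarity stays in the unit interval on random sentences in both dialects", {
  set.seed(29)
  th <- thresholds()
  ml <- modifier_lexicon(strong = rand_sentence_pool$strong,
                         weak = rand_sentence_pool$weak,
                         negatives = rand_sentence_pool$neg)
  for (i in 1:300) {
    df <- rand_tagged(12)
    sentdf <- rand_sent_table()
    sl <- sentiment_lexicon_from(sentdf$term, sentdf$pos, sentdf$pos_score,
                                 sentdf$neg_score, sentdf$obj_score)
    for (mode in c("calibrated", "as_printed")) {
      st <- detect_polarity(as_ts(df), integer(), ml, sl, th, mode = mode)
      expect_gte(st$polarity, 0)
      expect_lte(st$polarity, 1)
    }
  }
})

test_that("labels partition the unit interval", {
  th <- thresholds(theta_pos = 0.6, theta_neg = 0.4)
  expect_identical(classify_label(0.91, th), "positive")
  expect_identical(classify_label(0.49, th), "neutral")
  expect_identical(classify_label(0.1, th), "negative")
  expect_identical(classify_label(0.4, th), "neutral")  # closed band edges
  expect_identical(classify_label(0.6, th), "neutral")
  for (p in seq(0, 1, by = 0.01)) {
    lab <- classify_label(p, th)
    expect_true(lab %in% c("positive", "neutral", "negative"))
  }
  expect_identical(
    classify_label(list(polarity = 0.95, opinion_seen = FALSE), th),
    "no_opinion"
  )
  expect_error(thresholds(theta_pos = 0.3, theta_neg = 0.5))
})
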