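test_that("vocabulary loading case-folds, deduplicates and rejects empties", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Anxiety", "anxiety", "mood swings"), p)
  v <- load_vocabulary(p, "depression")
  expect_setequal(v$terms, c("anxiety", "mood swings"))
  expect_identical(v$condition, "depression")

  writeLines(c("# only", "# comments"), p)
  expect_error(load_vocabulary(p), class = "aspectrx_config_error")

  fifty <- sprintf("term%02d", 1:50)
  writeLines(sample(fifty), p)
  expect_setequal(load_vocabulary(p)$terms, fifty)
})

test_that("similarity is max-over-entries cosine with mean-vector terms", {
  toks <- c("mood", "swings", "anxiety", "sofa")
  emb <- basis_embedder(toks)
  vocab <- medical_vocabulary(c("mood", "swings", "anxiety"))
  # verbatim member of the vocabulary
  expect_equal(term_similarity("anxiety", vocab, emb), 1)
  # out of vocabulary under mutually orthogonal vectors
  expect_equal(term_similarity("sofa", vocab, emb), 0)
  # mean of orthogonal unit vectors against the best single entry:
  # cos((e1+e2)/2, e1) = (1/2) / (sqrt(1/2)) = 1/sqrt(2)
  expect_equal(term_similarity("mood swings", vocab, emb), 1 / sqrt(2),
               tolerance = 1e-12)
  # zero-vector sentinel on the term side
  expect_equal(term_similarity("unknownword", vocab, emb), 0)
})

test_that("filtering keeps the inclusive boundary and preserves order", {
  # construct a term whose best cosine is exactly 0.7
  emb <- structure(list(
    embed = function(token) {
      switch(tolower(token),
             anchor = c(1, 0, 0, 0, 0, 0, 0, 0),
             edge = c(0.7, sqrt(1 - 0.49), 0, 0, 0, 0, 0, 0),
             numeric(8))
    },
    dim = 8
  ), class = "hash_embedder")
  vocab <- medical_vocabulary("anchor")
  cands <- data.frame(surface = c("edge", "anchor", "nothing"),
                      rule = "single_noun", idx1 = 0:2, idx2 = NA_integer_,
                      stringsAsFactors = FALSE)
  out <- filter_candidates(cands, vocab, emb, threshold = 0.7)
  expect_equal(out$score, c(0.7, 1, 0), tolerance = 1e-12)
  expect_identical(out$kept, c(TRUE, TRUE, FALSE))
  expect_identical(out$surface, cands$surface)
  expect_identical(out$reason, c("", "", "oov_zero_vector"))
  all_kept <- filter_candidates(cands, vocab, emb, threshold = 0)
  expect_true(all(all_kept$kept))
})

test_that("in-vocabulary plants pass at 0.7 while orthogonal distractors fail", {
  emb <- hash_embedder(dim = 64, seed = 1)
  vocab <- medical_vocabulary(c("nausea", "headache", "mood swings"))
  cands <- data.frame(
    surface = c("nausea", "mood swings", "headache", "sofa", "carpet"),
    rule = "single_noun", idx1 = 0:4, idx2 = NA_integer_,
    stringsAsFactors = FALSE
  )
  out <- filter_candidates(cands, vocab, emb, threshold = 0.7)
  expect_identical(out$kept, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("raising the threshold never grows the kept set", {
  emb <- hash_embedder(dim = 32, seed = 4)
  vocab <- medical_vocabulary(sprintf("v%02d", 1:10))
  set.seed(31)
  cands <- data.frame(
    surface = sample(c(sprintf("v%02d", 1:10), sprintf("d%02d", 1:10)), 30,
                     replace = TRUE),
    rule = "single_noun", idx1 = 0:29, idx2 = NA_integer_,
    stringsAsFactors = FALSE
  )
  prev <- NULL
  for (th in seq(0, 1, by = 0.1)) {
    kept <- which(filter_candidates(cands, vocab, emb, th)$kept)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("adding the term itself to a vocabulary forces similarity 1", {
  emb <- hash_embedder(dim = 32, seed = 9)
  vocab <- medical_vocabulary(c("alpha", "beta"))
  for (term in c("gamma", "mood swings", "sofa")) {
    v2 <- medical_vocabulary(c(vocab$terms, term))
    expect_equal(term_similarity(term, v2, emb), 1, tolerance = 1e-12)
  }
})

test_that("hash embedder: deterministic, unit norm, synonym forcing", {
  emb <- hash_embedder(dim = 64, seed = 2,
                       synonym_table = data.frame(variant = "affects",
                                                  base = "effects"))
  expect_identical(emb$embed("nausea"), emb$embed("nausea"))
  expect_equal(sum(emb$embed("nausea")^2), 1, tolerance = 1e-12)
  expect_equal(sum(emb$embed("nausea") * emb$embed("nausea")), 1,
               tolerance = 1e-12)
  syn_cos <- sum(emb$embed("affects") * emb$embed("effects"))
  expect_gte(syn_cos, 0.9)
  # unrelated pairs concentrate near zero
  set.seed(12)
  pairs <- matrix(sample(sprintf("w%04d", 1:5000), 2000), ncol = 2)
  cosines <- apply(pairs, 1, function(pr) {
    sum(emb$embed(pr[1]) * emb$embed(pr[2]))
  })
  expect_lt(mean(abs(cosines)), 0.2)
  # embedding calls leave the caller's RNG stream untouched
  set.seed(77)
  a <- runif(1)
  set.seed(77)
  invisible(emb$embed("anything"))
  expect_identical(runif(1), a)
})
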