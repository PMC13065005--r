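test_that("token-overlap PRF follows the set definitions", {
  r <- token_prf(c("a", "b", "c", "d"), c("a", "b", "e"))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 1 / 2)
  expect_equal(r$f1, 4 / 7)
  perfect <- token_prf(c("x", "y"), c("y", "x"))
  expect_equal(unlist(perfect[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  expect_warning(z <- token_prf(c("a"), character()), "empty")
  expect_equal(unlist(z[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("PRF is symmetric up to swapping precision and recall", {
  set.seed(41)
  pool <- letters
  for (i in 1:50) {
    a <- sample(pool, sample(1:10, 1))
    p <- sample(pool, sample(1:10, 1))
    r1 <- token_prf(a, p)
    r2 <- token_prf(p, a)
    expect_equal(r1$precision, r2$recall)
    expect_equal(r1$recall, r2$precision)
    expect_equal(r1$f1, r2$f1)
  }
})

test_that("Cohen's kappa: identity, independence, brute-force agreement", {
  expect_equal(cohens_kappa(c("P", "N", "P"), c("P", "N", "P"))$kappa, 1)
  r <- cohens_kappa(c("P", "P", "N", "N"), c("P", "N", "P", "N"))
  expect_equal(r$observed_agreement, 0.5)
  expect_equal(r$expected_agreement, 0.5)
  expect_equal(r$kappa, 0)
  # both raters constant and equal: agreement is perfect by convention
  expect_equal(cohens_kappa(rep("P", 5), rep("P", 5))$kappa, 1)
  set.seed(43)
  for (i in 1:100) {
    cats <- sample(2:4, 1)
    a <- sample(LETTERS[1:cats], 200, replace = TRUE)
    b <- sample(LETTERS[1:cats], 200, replace = TRUE)
    expect_equal(cohens_kappa(a, b)$kappa, oracle_cohen(a, b),
                 tolerance = 1e-12)
  }
  expect_error(cohens_kappa(c("a", "b"), c("a")),
               class = "aspectrx_contract_error")
})

test_that("kappa is invariant under relabeling", {
  set.seed(47)
  a <- sample(c("pos", "neu", "neg"), 120, replace = TRUE)
  b <- sample(c("pos", "neu", "neg"), 120, replace = TRUE)
  perm <- c(pos = "X", neu = "Y", neg = "Z")
  expect_equal(cohens_kappa(a, b)$kappa,
               cohens_kappa(perm[a], perm[b])$kappa, tolerance = 1e-12)
})

test_that("Fleiss' kappa: unanimity, hand formula, below-chance structure", {
  unan <- matrix(c(3, 0, 0, 3, 3, 0), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(unan)$kappa, 1)
  m <- matrix(c(2, 1, 0,
                0, 3, 0,
                1, 1, 1,
                3, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(fleiss_kappa(m)$kappa, oracle_fleiss(m), tolerance = 1e-12)
  set.seed(53)
  for (i in 1:100) {
    n_items <- sample(3:10, 1)
    n_raters <- sample(2:5, 1)
    n_cats <- sample(2:4, 1)
    mm <- t(vapply(seq_len(n_items), function(j) {
      tabulate(sample(n_cats, n_raters, replace = TRUE), n_cats)
    }, integer(n_cats)))
    expect_equal(fleiss_kappa(mm)$kappa, oracle_fleiss(mm),
                 tolerance = 1e-12)
  }
  # every category equally filled on every item: below-chance agreement
  eq <- matrix(1, nrow = 4, ncol = 3)
  expect_lte(fleiss_kappa(eq)$kappa, 0)
  expect_error(fleiss_kappa(matrix(c(2, 1, 3, 1), ncol = 2, byrow = TRUE)),
               class = "aspectrx_contract_error")
})

test_that("majority vote needs a strict majority and ignores order", {
  expect_identical(majority_vote(c("pos", "pos", "pos")), "pos")
  expect_identical(majority_vote(c("pos", "neg", "pos")), "pos")
  expect_identical(majority_vote(c("pos", "neg", "neutral")), "unresolved")
  expect_identical(majority_vote(c("pos", "neg", "pos", "neg")), "unresolved")
  set.seed(59)
  for (i in 1:50) {
    labs <- sample(c("a", "b", "c"), 5, replace = TRUE)
    expect_identical(majority_vote(labs), majority_vote(sample(labs)))
  }
  expect_error(majority_vote(c("a", "b"), n_annotators = 3),
               class = "aspectrx_contract_error")
})

test_that("token classes mark uni- and bi-word aspect membership", {
  ts <- tagged_sentence(sprintf("w%d", 1:6), rep("NOUN", 6), rep("dep", 6))
  two <- data.frame(surface = "w2 w3", rule = "compound_pair",
                    idx1 = 1L, idx2 = 2L)
  expect_identical(token_classes(ts, two),
                   c("non_aspect", "bi_word", "bi_word", rep("non_aspect", 3)))
  expect_identical(token_classes(ts, two[0, ]), rep("non_aspect", 6))
  mixed <- data.frame(surface = c("w1", "w4 w5"),
                      rule = c("single_noun", "compound_pair"),
                      idx1 = c(0L, 3L), idx2 = c(NA, 4L))
  cls <- token_classes(ts, mixed)
  expect_identical(sum(cls == "non_aspect"), 3L)
  expect_identical(sum(cls == "uni_word"), 1L)
  expect_identical(sum(cls == "bi_word"), 2L)
  # overlap resolves in favour of the two-token aspect
  both <- data.frame(surface = c("w2", "w2 w3"),
                     rule = c("single_noun", "compound_pair"),
                     idx1 = c(1L, 1L), idx2 = c(NA, 2L))
  expect_identical(token_classes(ts, both)[2], "bi_word")
})

test_that("per-class report equals a confusion-matrix oracle", {
  set.seed(61)
  classes <- c("non_aspect", "uni_word", "bi_word")
  gold <- sample(classes, 100, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  pred <- gold
  flip <- sample(100, 20)
  pred[flip] <- sample(classes, 20, replace = TRUE)
  rep_ <- per_class_report(gold, pred, classes = classes)
  for (cl in classes) {
    want <- oracle_per_class(gold, pred, cl)
    row <- rep_[rep_$class == cl, ]
    expect_equal(c(row$precision, row$recall, row$f1), unname(want),
                 tolerance = 1e-12)
  }
  same <- per_class_report(gold, gold, classes = classes)
  expect_true(all(same$precision == 1 & same$recall == 1 & same$f1 == 1))
  expect_warning(
    single <- per_class_report(rep("a", 5), rep("a", 5),
                               classes = c("a", "b")),
    "absent"
  )
  expect_equal(single$f1[single$class == "b"], 0)
})
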