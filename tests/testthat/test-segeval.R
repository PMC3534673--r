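test_that("scoring matches hand counts", {
  lex <- make_lexicon(c("a b", "c d", "e f"), c(5, 4, 3))
  corp <- make_corpus(lex, list(c(1, 2, 3)))  # 6 syllables, gold {2, 4}
  r <- make_response(corp, list(c(2, 5)))
  sc <- score_segmentation(r, corp)
  expect_equal(sc$hits, 1L)
  expect_equal(sc$false_alarms, 1L)
  expect_equal(sc$misses, 1L)
  expect_equal(sc$precision, 0.5)
  expect_equal(sc$recall, 0.5)
  expect_equal(sc$f_score, 0.5)

  identity <- make_response(corp, corp$gold_gaps)
  expect_equal(score_segmentation(identity, corp)$f_score, 1)
  empty <- make_response(corp, list(integer(0)))
  sc0 <- score_segmentation(empty, corp)
  expect_equal(sc0$hits, 0L)
  expect_equal(sc0$recall, 0)
  expect_equal(sc0$f_score, 0)

  mismatched <- make_response(corp, list(c(2)))
  mismatched$n_syllables <- 4L
  expect_error(score_segmentation(mismatched, corp), "mismatch")
})

test_that("count identities hold for arbitrary random responses", {
  lang <- small_language()
  K <- sum(lengths(lang$test$gold_gaps))
  set.seed(99)
  for (i in 1:10) {
    gaps <- lapply(lang$test$n_syllables, function(L) {
      G <- L - 1L
      sort(sample.int(G, sample.int(G + 1L, 1) - 1L))
    })
    r <- make_response(lang$test, gaps)
    sc <- score_segmentation(r, lang$test)
    expect_equal(sc$hits + sc$misses, K)
    expect_equal(sc$hits + sc$false_alarms, sum(lengths(gaps)))
    if (sc$precision > 0 && sc$recall > 0) {
      expect_gte(sc$f_score, min(sc$precision, sc$recall) - 1e-12)
      expect_lte(sc$f_score, (sc$precision + sc$recall) / 2 + 1e-12)
    }
  }
})

test_that("location decisions carry the governing word's frequency", {
  lex <- make_lexicon(c("a b", "c d e"), c(100, 7000))
  corp <- make_corpus(lex, list(c(1, 2)))  # gold gap {2}; 5 syllables
  r <- make_response(corp, list(c(2, 4)))
  d <- classify_locations(r, corp, lex)
  expect_equal(nrow(d), 4L)
  # boundary gap gets the higher adjacent frequency
  expect_equal(d$freq_label[d$is_boundary], 7000L)
  # internal gaps of the 3-syllable word carry its own frequency
  expect_equal(d$freq_label[d$gap %in% c(3, 4)], c(7000L, 7000L))
  expect_equal(d$freq_label[d$gap == 1], 100L)
  expect_equal(d$correct, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(d$log_freq, log(d$freq_label))
})

test_that("word-internal gaps outnumber boundary gaps at mean word length 3", {
  lang <- small_language()
  r <- oracle_noisy_segmenter(lang$test, 1, 0)
  d <- classify_locations(r, lang$test, lang$lexicon)
  expect_gt(sum(!d$is_boundary), sum(d$is_boundary))
})

test_that("binned accuracy is flat for the noisy oracle and 1 when perfect", {
  lang <- small_language(seed = 5, n_test = 150L)
  perfect <- classify_locations(oracle_noisy_segmenter(lang$test, 1, 0),
                                lang$test, lang$lexicon)
  b <- bin_by_log_frequency(perfect, n_bins = 5)
  expect_true(all(b$prop_correct == 1))
  expect_true(all(b$ci_high < 1 & b$ci_low > 0))

  h <- 0.7
  noisy <- classify_locations(oracle_noisy_segmenter(lang$test, h, 0.1, seed = 3),
                              lang$test, lang$lexicon)
  bb <- bin_by_log_frequency(noisy, n_bins = 4)
  bnd <- bb[bb$is_boundary & bb$n >= 20, ]
  for (i in seq_len(nrow(bnd))) {
    expect_lt(abs(bnd$prop_correct[i] - h), 3 * sqrt(h * (1 - h) / bnd$n[i]) + 0.02)
  }
})

test_that("permutation expected hits match exhaustive enumeration when G <= 8", {
  # single sentence, G = 4 gaps, k = 2 true boundaries, m = 2 marks:
  # enumerate all C(4,2) = 6 placements
  gold <- c(2, 4)
  placements <- utils::combn(4, 2, simplify = FALSE)
  mean_hits <- mean(vapply(placements, function(p) length(intersect(p, gold)), 0))
  expect_equal(mean_hits, 2 * 2 / 4)  # closed form m k / G

  lex <- make_lexicon(c("a b", "c d", "e"), c(3, 3, 3))
  corp <- make_corpus(lex, list(c(1, 2, 3)))  # 5 syllables, G = 4, gold {2,4}
  r <- make_response(corp, list(c(1, 3)))
  base <- permutation_baseline(r, corp, n_reps = 4000, seed = 8)
  # mean permuted F maps back to mean hits: F = 2H/(m+k)
  mc_hits <- mean(base$f_samples) * (2 + 2) / 2
  expect_lt(abs(mc_hits - mean_hits), 3 * stats::sd(base$f_samples * 2) / sqrt(4000))
})

test_that("permutation baseline preserves mark counts and flags perfect responses", {
  lang <- small_language()
  r <- oracle_noisy_segmenter(lang$test, 1, 0)
  base <- permutation_baseline(r, lang$test, n_reps = 2000, seed = 4)
  expect_equal(base$observed_f, 1)
  expect_gt(base$observed_f, base$ci_high)
  expect_lt(base$p_value, 0.01)
  expect_equal(base$sentences$m, lengths(r$gaps))
  expect_true(all(base$f_samples >= 0 & base$f_samples <= 1))
  # m = 0 everywhere: the null is degenerate at F = 0
  silent <- make_response(lang$test, lapply(lang$test$sentence_id, function(i) integer(0)))
  b0 <- permutation_baseline(silent, lang$test, n_reps = 50, seed = 1)
  expect_true(all(b0$f_samples == 0))
  # more marks than gaps is rejected
  bad <- make_response(lang$test[1, ], list(seq_len(lang$test$n_syllables[1] + 3L)))
  expect_error(permutation_baseline(bad, lang$test[1, ], 10, 1), "more marks")
})

test_that("explicit gap shuffles agree with the hypergeometric engine", {
  gold <- c(2, 4)
  set.seed(12)
  hits <- replicate(4000, length(intersect(permute_gaps(4, 2), gold)))
  expect_lt(abs(mean(hits) - 1), 3 * stats::sd(hits) / sqrt(4000))
  expect_error(permute_gaps(3, 5), "more marks")
})

test_that("a random segmenter is indistinguishable from its own null", {
  lang <- small_language()
  set.seed(2024)
  pvals <- vapply(1:30, function(i) {
    gaps <- mapply(function(L, gold) sort(sample.int(L - 1L, length(gold))),
                   lang$test$n_syllables, lang$test$gold_gaps, SIMPLIFY = FALSE)
    r <- make_response(lang$test, gaps)
    permutation_baseline(r, lang$test, n_reps = 400,
                         seed = 5000 + i)$p_value
  }, 0)
  # calibration: p-values roughly uniform
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals), 0.75)
  expect_gt(mean(pvals > 0.05), 0.7)
})

test_that("degeneracy detector flags exactly the fixed-period responders", {
  lang <- small_language()
  for (p in c(1, 2, 3)) {
    flag <- detect_degenerate_strategy(periodic_segmenter(lang$test, p))
    expect_true(flag$flagged)
    expect_equal(flag$period, p)
  }
  noisy <- oracle_noisy_segmenter(lang$test, 0.6, 0.1, seed = 6)
  expect_false(detect_degenerate_strategy(noisy)$flagged)
  empty <- make_response(lang$test, lapply(lang$test$sentence_id, function(i) integer(0)))
  flag <- detect_degenerate_strategy(empty)
  expect_true(flag$flagged)
  expect_equal(flag$period, Inf)
})
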