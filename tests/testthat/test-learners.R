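test_that("noisy oracle at the extremes reproduces gold or stays silent", {
  lang <- small_language()
  perfect <- oracle_noisy_segmenter(lang$test, 1, 0)
  expect_identical(lapply(perfect$gaps, as.integer),
                   lapply(lang$test$gold_gaps, as.integer))
  expect_equal(score_segmentation(perfect, lang$test)$f_score, 1)
  silent <- oracle_noisy_segmenter(lang$test, 0, 0)
  expect_true(all(lengths(silent$gaps) == 0L))
  sc <- score_segmentation(silent, lang$test)
  expect_equal(sc$recall, 0)
  expect_equal(sc$f_score, 0)
})

test_that("noisy oracle empirical rates concentrate on the parameters", {
  lang <- small_language(seed = 21, n_test = 200L)
  r <- oracle_noisy_segmenter(lang$test, 0.6, 0.1, seed = 77)
  hits <- sum(mapply(function(p, g) length(intersect(p, g)), r$gaps, lang$test$gold_gaps))
  k <- sum(lengths(lang$test$gold_gaps))
  fa <- sum(lengths(r$gaps)) - hits
  internal <- sum(lang$test$n_syllables - 1L) - k
  expect_lt(abs(hits / k - 0.6), 3 * sqrt(0.6 * 0.4 / k))
  expect_lt(abs(fa / internal - 0.1), 3 * sqrt(0.1 * 0.9 / internal))
})

test_that("transitional probabilities match hand counts on toy corpora", {
  toy <- toy_language()
  tp <- estimate_tp(toy$training)
  p_of <- function(a, b) tp$p[tp$s1 == a & tp$s2 == b]
  expect_equal(p_of("s1", "s2"), 1)           # within word A
  expect_equal(p_of("s3", "s4"), 1)           # within word B
  expect_equal(p_of("s2", "s3"), 0.5)         # across-word transition
  rows <- tapply(tp$p, tp$s1, sum)
  expect_equal(as.vector(rows), rep(1, length(rows)))

  single <- make_corpus(make_lexicon("pa ta", 1), list(1L))
  tp1 <- estimate_tp(single)
  expect_equal(nrow(tp1), 1L)
  expect_equal(tp1$p, 1)
})

test_that("TP segmenter achieves F = 1 when a threshold separates the TPs", {
  toy <- toy_language()
  tp <- estimate_tp(toy$training)
  across_max <- max(tp$p[tp$p < 1])
  r <- tp_segmenter(toy$test, tp, tp_threshold = (across_max + 1) / 2)
  expect_equal(score_segmentation(r, toy$test)$f_score, 1)
})

test_that("TP threshold extremes mark nothing or everything", {
  lang <- small_language()
  tp <- estimate_tp(lang$training)
  none <- tp_segmenter(lang$test, tp, tp_threshold = 0)
  expect_true(all(lengths(none$gaps) == 0L))
  all_marks <- tp_segmenter(lang$test, tp, tp_threshold = 1 + 1e-9)
  expect_equal(lengths(all_marks$gaps), pmax(lang$test$n_syllables - 1L, 0L))
  sc <- score_segmentation(all_marks, lang$test)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision,
               sum(lengths(lang$test$gold_gaps)) / sum(lang$test$n_syllables - 1L))
})

test_that("unseen bigrams at test are treated as zero-probability junctures", {
  lex <- make_lexicon(c("pa ta", "ko mu"), c(5, 5))
  train <- make_corpus(lex, list(c(1, 2, 1)), role = "training")
  test <- make_corpus(make_lexicon(c("pa ta", "zz qq"), c(5, 5)), list(c(1, 2)))
  r <- tp_segmenter(test, estimate_tp(train), tp_threshold = 0.05)
  expect_true(2L %in% r$gaps[[1]])  # ta->zz never seen: marked
})

test_that("yoked control underperforms a trained TP segmenter on the same block", {
  lang <- generate_language(n_types = 200, total_tokens = 8000, floor = 3,
                            n_test_sentences = 150, seed = 31)
  trained <- tp_segmenter(lang$test, estimate_tp(lang$training))
  yoked <- yoked_control_segmenter(lang$test)
  f_trained <- score_segmentation(trained, lang$test)$f_score
  f_yoked <- score_segmentation(yoked, lang$test)$f_score
  expect_gt(f_trained, f_yoked)
  empty <- lang$test[0, ]
  expect_equal(nrow(yoked_control_segmenter(empty)), 0L)
})

test_that("periodic segmenter lays an exact lattice", {
  lex <- make_lexicon(c("a b", "c d", "e f"), c(3, 3, 3))
  corp <- make_corpus(lex, list(c(1, 2, 3), c(1, 2)))
  r <- periodic_segmenter(corp, period = 2)
  expect_equal(r$gaps[[1]], c(2L, 4L))
  expect_equal(r$gaps[[2]], 2L)
  r9 <- periodic_segmenter(corp, period = 9)
  expect_true(all(lengths(r9$gaps) == 0L))
  expect_true(detect_degenerate_strategy(r)$flagged)
})

test_that("chunk segmenter parses leftmost-longest and improves with training", {
  toy <- toy_language()
  r <- chunk_segmenter(toy$test, toy$training, n_chunks = 9, max_len = 2)
  # both words are top chunks, so the parse recovers all boundaries
  expect_equal(score_segmentation(r, toy$test)$recall, 1)
})

test_that("2AFC responder respects the half-logit floor and ceiling", {
  trials <- tibble::tibble(trial = 1:400,
                           target_freq = rep(c(10, 100, 1000, 8000), 100),
                           log_target_freq = log(rep(c(10, 100, 1000, 8000), 100)))
  floor_resp <- twoafc_responder(trials, beta0 = -50, beta1 = 0, seed = 2)
  expect_lt(abs(mean(floor_resp$chose_target) - 0.5), 3 * sqrt(0.25 / 400))
  ceiling_resp <- twoafc_responder(trials, beta0 = 50, beta1 = 0, seed = 2)
  expect_true(all(ceiling_resp$chose_target))
  expect_true(all(floor_resp$p_correct >= 0.5 & floor_resp$p_correct <= 1))
})

test_that("responses serialize to one CSV line per sentence", {
  lang <- small_language()
  r <- oracle_noisy_segmenter(lang$test, 1, 0)
  lines <- write_response_csv(r)
  expect_length(lines, nrow(lang$test) + 1L)
  expect_match(lines[1], "participant,condition,sentence_id,gaps")
  expect_match(lines[2], "^oracle,trained,1,")
})
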