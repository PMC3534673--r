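test_that("syllable inventory is the full Cartesian product", {
  inv <- build_syllable_inventory(default_phonology())
  expect_equal(nrow(inv), 336)
  expect_equal(anyDuplicated(inv$syllable), 0L)
  # consonant-major order: first vowel cycles fastest
  expect_equal(inv$consonant[1:14], rep(default_phonology()$consonants[1], 14))

  cases <- list(c(1, 1, 1), c(2, 3, 6), c(5, 4, 20))
  for (cs in cases) {
    ph <- list(consonants = paste0("c", seq_len(cs[1])),
               vowels = paste0("v", seq_len(cs[2])))
    expect_equal(nrow(build_syllable_inventory(ph)), cs[3])
  }
  expect_error(build_syllable_inventory(list(consonants = c("a", "a"), vowels = "e")),
               "unique")
  expect_error(build_syllable_inventory(list(consonants = character(0), vowels = "e")),
               "non-empty")
})

test_that("Zipf allocation matches the closed-form solve on a tiny case", {
  # oracle: with two ranks and no floor, C (1 + 1/2) = 30 gives C = 20,
  # hence counts (20, 10)
  alloc <- allocate_zipf_counts(2, 30, floor = 0)
  expect_equal(alloc$count, c(20L, 10L))
})

test_that("Zipf allocation invariants hold across configurations", {
  cases <- list(c(1000, 60000, 10), c(100, 5000, 3), c(7, 100, 0),
                c(50, 50, 1), c(3, 1000, 0))
  for (cs in cases) {
    a <- allocate_zipf_counts(cs[1], cs[2], cs[3])
    expect_equal(sum(a$count), cs[2])
    expect_false(is.unsorted(rev(a$count)))
    expect_true(all(a$count >= cs[3]))
  }
  expect_error(allocate_zipf_counts(10, 5, floor = 1), "Infeasible")
})

test_that("unfloored counts track C/r to within rounding", {
  a <- allocate_zipf_counts(500, 100000, floor = 0)
  C <- attr(a, "scale_C")
  r <- a$rank[-1]  # rank 1 absorbs the rounding residual
  expect_true(all(abs(a$count[-1] * r - C) <= r / 2 + 1e-6))
})

test_that("lexicon has unique forms, shifted-Poisson lengths, and is reproducible", {
  inv <- build_syllable_inventory(default_phonology())
  alloc <- allocate_zipf_counts(1000, 60000, 10)
  lex <- build_lexicon(inv, alloc, seed = 42)
  expect_equal(nrow(lex), 1000)
  expect_equal(anyDuplicated(lex$form), 0L)
  expect_true(all(lex$length >= 1))
  expect_equal(lex$length, lengths(lex$syllables))
  expect_equal(lex$frequency, alloc$count)
  # mean length ~ 3 within 3 Monte-Carlo SEs of a shifted Poisson(2) + 1
  se <- sqrt(2 / 1000)
  expect_lt(abs(mean(lex$length) - 3), 3 * se)
  expect_identical(lex$form, build_lexicon(inv, alloc, seed = 42)$form)
  expect_false(identical(lex$form, build_lexicon(inv, alloc, seed = 43)$form))
  # degenerate length distribution: all mass at one syllable
  lex1 <- build_lexicon(inv, allocate_zipf_counts(50, 500, 1), length_mean = 1, seed = 1)
  expect_true(all(lex1$length == 1L))
})

test_that("training corpus realizes counts exactly with no immediate repetition", {
  lang <- small_language()
  stream <- unlist(lang$training$words)
  expect_equal(length(stream), 1500L)
  tab <- tabulate(stream, nbins = 60L)
  expect_equal(tab, lang$allocation$count)
  expect_false(any(stream[-1] == stream[-length(stream)]))
  expect_true(all(lang$training$n_words >= 2))
})

test_that("sentence structure invariants hold", {
  lang <- small_language()
  for (corp in list(lang$training, lang$test)) {
    len <- lapply(corp$words, function(w) lang$lexicon$length[w])
    expect_equal(corp$n_syllables, vapply(len, sum, 0L))
    expect_equal(lengths(corp$gold_gaps), corp$n_words - 1L)
    ok <- mapply(function(g, L) all(g >= 1 & g <= L - 1) && !is.unsorted(g),
                 corp$gold_gaps, corp$n_syllables)
    expect_true(all(ok))
  }
})

test_that("two equally frequent words arrange into strict alternation", {
  lex <- make_lexicon(c("pa ta", "ko mu"), c(12, 12))
  attr(lex, "allocation") <- tibble::tibble(rank = 1:2, count = c(12L, 12L))
  corp <- generate_corpus(lex, sentlen_mean = 4, seed = 5)
  stream <- unlist(corp$words)
  expect_true(all(stream[-1] != stream[-length(stream)]))
  expect_equal(sort(unique(diff(which(stream == 1)))), 2L)
})

test_that("adjacency-unsatisfiable allocations are rejected", {
  lex <- make_lexicon(c("pa", "ko"), c(10, 2))
  expect_error(generate_corpus(lex, seed = 1), "unsatisfiable")
})

test_that("multinomial mode hits the token total without immediate repeats", {
  lang <- small_language()
  corp <- generate_corpus(lang$lexicon, seed = 9, exact_counts = FALSE)
  stream <- unlist(corp$words)
  expect_equal(length(stream), 1500L)
  expect_false(any(stream[-1] == stream[-length(stream)]))
})

test_that("test blocks are novel, sized as configured, and seeded", {
  lang <- small_language()
  train_keys <- vapply(lang$training$words, paste, "", collapse = " ")
  test_keys <- vapply(lang$test$words, paste, "", collapse = " ")
  expect_length(test_keys, 30L)
  expect_equal(length(intersect(test_keys, train_keys)), 0L)
  empty <- generate_test_block(lang$lexicon, lang$training, 0, seed = 1)
  expect_equal(nrow(empty), 0L)
  again <- generate_test_block(lang$lexicon, lang$training, 30, seed = attr(lang$test, "seed"))
  expect_identical(again$words, lang$test$words)
})

test_that("corpus means converge to their configured values over seeds", {
  wl <- sl <- ss <- numeric(6)
  for (i in seq_along(wl)) {
    lang <- generate_language(n_types = 200, total_tokens = 6000, floor = 3,
                              n_test_sentences = 0, seed = 300 + i)
    wl[i] <- mean(lang$lexicon$length)
    sl[i] <- mean(lang$training$n_words)
    ss[i] <- mean(lang$training$n_syllables)
  }
  expect_lt(abs(mean(wl) - 3), 3 * stats::sd(wl) / sqrt(6) + 0.05)
  expect_lt(abs(mean(sl) - 4), 3 * stats::sd(sl) / sqrt(6) + 0.05)
  expect_lt(abs(mean(ss) - 12), 3 * stats::sd(ss) / sqrt(6) + 0.6)
})
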