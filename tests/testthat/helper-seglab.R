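# Shared fixtures, built in code.

# Hand-built lexicon from explicit forms (space-separated syllables).
make_lexicon <- function(forms, freqs) {
  syl <- strsplit(forms, " ", fixed = TRUE)
  lex <- tibble::tibble(
    rank = seq_along(forms),
    form = forms,
    length = lengths(syl),
    frequency = as.integer(freqs),
    syllables = syl
  )
  attr(lex, "inventory") <- unique(unlist(syl))
  lex
}

# Hand-built corpus from a lexicon and explicit word-rank sequences.
make_corpus <- function(lexicon, word_seqs, role = "test") {
  rows <- lapply(word_seqs, function(w) {
    len <- lexicon$length[match(w, lexicon$rank)]
    list(words = w,
         syllables = unlist(lexicon$syllables[match(w, lexicon$rank)], use.names = FALSE),
         gold = if (length(w) > 1L) cumsum(len)[-length(len)] else integer(0))
  })
  out <- tibble::tibble(
    sentence_id = seq_along(rows),
    words = lapply(rows, `[[`, "words"),
    syllables = lapply(rows, `[[`, "syllables"),
    n_words = lengths(word_seqs),
    n_syllables = vapply(rows, function(r) length(r$syllables), 0L),
    gold_gaps = lapply(rows, `[[`, "gold")
  )
  attr(out, "role") <- role
  attr(out, "token_total") <- sum(out$n_words)
  out
}

# Hand-built response from explicit gap sets.
make_response <- function(corpus, gap_sets, participant = "p", condition = "trained") {
  tibble::tibble(
    participant = participant, condition = condition,
    sentence_id = corpus$sentence_id,
    n_syllables = corpus$n_syllables,
    gaps = lapply(gap_sets, as.integer)
  )
}

# A small language for fast unit tests.
small_language <- function(seed = 11, n_test = 30L) {
  generate_language(n_types = 60L, total_tokens = 1500L, floor = 3L,
                    n_test_sentences = n_test, seed = seed)
}

# One full-scale language, generated once per test run and shared.
.paper_cache <- new.env(parent = emptyenv())
paper_language <- function(seed = 101) {
  key <- paste0("lang", seed)
  if (!exists(key, envir = .paper_cache)) {
    assign(key, generate_language(seed = seed), envir = .paper_cache)
  }
  get(key, envir = .paper_cache)
}

# Toy three-word language (A = "s1 s2", B = "s3 s4", C = "s5 s6"): the
# training corpus covers every ordered word pair, so within-word TPs are 1
# and across-word TPs are 1/2 — any threshold in between recovers every
# boundary exactly.
toy_language <- function() {
  lex <- make_lexicon(c("s1 s2", "s3 s4", "s5 s6"), c(10, 10, 10))
  train <- make_corpus(lex, list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2),
                                 c(1, 3, 2), c(2, 3, 1), c(3, 2, 1)),
                       role = "training")
  test <- make_corpus(lex, list(c(1, 2, 1), c(2, 3, 1, 3)))
  list(lexicon = lex, training = train, test = test)
}
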