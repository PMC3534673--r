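# Language generation: CV syllable inventory, floored Zipfian lexicon,
# training corpus, and novel-sentence test blocks.

#' Default phoneme inventory
#'
#' 24 consonant and 14 vowel labels, combining to a 336-syllable CV
#' inventory. Labels are SAMPA-like and unambiguous as plain text.
#'
#' @return A list with character vectors `consonants` and `vowels`.
#' @export
default_phonology <- function() {
  list(
    consonants = c("p", "b", "t", "d", "k", "g", "f", "v", "s", "z",
                   "S", "Z", "h", "m", "n", "N", "l", "r", "w", "j",
                   "tS", "dZ", "T", "D"),
    vowels = c("a", "e", "i", "o", "u", "A", "E", "I", "O", "U",
               "y", "@", "aj", "aw")
  )
}

#' Build the CV syllable inventory
#'
#' Takes the full Cartesian product of consonant and vowel labels in
#' consonant-major order, so 24 consonants x 14 vowels give the canonical
#' 336 CV syllables.
#'
#' @param phonology A list with character vectors `consonants` and `vowels`
#'   (labels unique within each list); see [default_phonology()].
#' @return A tibble with columns `syllable`, `consonant`, `vowel`, one row
#'   per CV combination.
#' @export
#' @examples
#' inv <- build_syllable_inventory(default_phonology())
#' nrow(inv) # 336
build_syllable_inventory <- function(phonology = default_phonology()) {
  cons <- phonology$consonants
  vows <- phonology$vowels
  if (length(cons) == 0L || length(vows) == 0L) {
    abort("Both consonant and vowel lists must be non-empty.")
  }
  if (anyDuplicated(cons) || anyDuplicated(vows)) {
    abort("Phoneme labels must be unique within each list.")
  }
  grid <- expand.grid(vowel = vows, consonant = cons,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  inv <- tibble::tibble(
    syllable = paste0(grid$consonant, grid$vowel),
    consonant = grid$consonant,
    vowel = grid$vowel
  )
  if (anyDuplicated(inv$syllable)) {
    abort("Phoneme labels produce duplicate syllables; use unambiguous labels.")
  }
  inv
}

#' Allocate per-rank token counts under a floored Zipfian distribution
#'
#' Solves numerically for the Zipf scale constant C such that the per-rank
#' counts `max(round(C / r), floor)` over ranks `r = 1..n_types` sum to
#' `total_tokens`; any residual left by rounding is absorbed by rank 1.
#' The floor guarantees every type a minimum number of tokens (the tail of a
#' pure 1/r law would otherwise fall below it).
#'
#' @param n_types Number of word types (ranks).
#' @param total_tokens Total token count the counts must sum to exactly.
#' @param floor Minimum tokens per type.
#' @return A tibble with columns `rank` and `count`, non-increasing in rank,
#'   with attributes `scale_C`, `floor`, `total_tokens`.
#' @export
#' @examples
#' alloc <- allocate_zipf_counts(1000, 60000, floor = 10)
#' alloc$count[1]    # ~8000
#' min(alloc$count)  # 10
allocate_zipf_counts <- function(n_types, total_tokens, floor = 10L) {
  n_types <- assert_count(n_types, "n_types", min = 1L)
  total_tokens <- assert_count(total_tokens, "total_tokens", min = 1L)
  floor <- assert_count(floor, "floor", min = 0L)
  if (n_types * floor > total_tokens) {
    abort(sprintf("Infeasible floor: %d types x floor %d exceeds %d tokens.",
                  n_types, floor, total_tokens))
  }
  r <- seq_len(n_types)
  total_at <- function(C) sum(pmax(round(C / r), floor))
  # total_at is non-decreasing in C; bisect to the smallest C reaching the total
  lo <- 0
  hi <- as.double(total_tokens)
  while (total_at(hi) < total_tokens) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (total_at(mid) < total_tokens) lo <- mid else hi <- mid
  }
  C <- hi
  counts <- pmax(round(C / r), floor)
  counts[1] <- counts[1] + (total_tokens - sum(counts))
  counts <- as.integer(counts)
  if (is.unsorted(rev(counts)) || any(counts < floor) || sum(counts) != total_tokens) {
    abort("Internal error: Zipf allocation failed its own invariants.")
  }
  out <- tibble::tibble(rank = r, count = counts)
  attr(out, "scale_C") <- C
  attr(out, "floor") <- floor
  attr(out, "total_tokens") <- total_tokens
  out
}

#' Build a lexicon of unique random word forms with Zipfian frequencies
#'
#' Word lengths (in syllables) are drawn i.i.d. from a shifted Poisson,
#' `Poisson(length_mean - 1) + 1`, so lengths of zero cannot occur; with the
#' default `length_mean = 3` this is Poisson(2) + 1. Forms are uniform random
#' syllable sequences of the drawn length, resampled on collision until all
#' forms are pairwise distinct. Length and frequency are assigned
#' independently: there is no bias for frequent words to be short.
#'
#' @param inventory Syllable inventory tibble from [build_syllable_inventory()].
#' @param allocation Zipf allocation tibble from [allocate_zipf_counts()].
#' @param length_mean Mean word length in syllables (>= 1).
#' @param seed Integer seed; the same seed reproduces the lexicon exactly.
#' @param max_resample Resampling budget per entry before giving up.
#' @return A tibble with columns `rank`, `form` (space-joined syllables),
#'   `length`, `frequency`, and list-column `syllables`; attributes
#'   `inventory`, `allocation`, `seed`.
#' @export
build_lexicon <- function(inventory, allocation, length_mean = 3, seed = 1L,
                          max_resample = 1000L) {
  stopifnot(is.data.frame(inventory), "syllable" %in% names(inventory))
  stopifnot(is.data.frame(allocation), all(c("rank", "count") %in% names(allocation)))
  if (length_mean < 1) abort("`length_mean` must be >= 1.")
  syls <- inventory$syllable
  n <- nrow(allocation)
  with_substream(substream_seed(seed, "lexicon"), {
    lens <- rpois(n, length_mean - 1) + 1L
    seen <- new.env(hash = TRUE, parent = emptyenv())
    forms <- vector("list", n)
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        f <- sample(syls, lens[i], replace = TRUE)
        key <- paste(f, collapse = " ")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          forms[[i]] <- f
          break
        }
        tries <- tries + 1L
        if (tries >= max_resample) {
          abort(sprintf(
            "Could not draw a unique form of length %d after %d tries; too few distinct forms at this length.",
            lens[i], max_resample))
        }
      }
    }
  })
  out <- tibble::tibble(
    rank = allocation$rank,
    form = vapply(forms, paste, "", collapse = " "),
    length = lens,
    frequency = allocation$count,
    syllables = forms
  )
  attr(out, "inventory") <- inventory$syllable
  attr(out, "allocation") <- allocation
  attr(out, "seed") <- seed
  out
}

# Constrained greedy arrangement: pick each next token at random among the
# types with remaining supply, never repeating the previous pick, and taking
# a type by force once its remaining count reaches (slots left + 1) / 2
# (delaying it any further would force a repeat). Exact but O(n * types);
# used for tight multisets where swap repair stalls.
arrange_greedy <- function(tokens) {
  counts <- tabulate(tokens)
  n <- length(tokens)
  out <- integer(n)
  prev <- 0L
  for (i in seq_len(n)) {
    left <- n - i + 1L
    forced <- which(counts * 2L >= left + 1L)
    if (length(forced) && forced[1] != prev) {
      pick <- forced[1]
    } else {
      ok <- which(counts > 0L)
      ok <- ok[ok != prev]
      if (length(ok) == 0L) {
        abort("Adjacency constraint unsatisfiable for this token multiset.")
      }
      pick <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = counts[ok])
    }
    out[i] <- pick
    counts[pick] <- counts[pick] - 1L
    prev <- pick
  }
  out
}

# Arrange a token multiset into a random order with no two equal neighbours.
# Random shuffle followed by swap repair: each offending position is swapped
# with a random position where neither side gains an equal neighbour. Falls
# back to the constrained greedy arrangement when repair stalls (tight
# multisets close to forced alternation).
arrange_no_repeat <- function(tokens, max_sweeps = 100L) {
  n <- length(tokens)
  if (n < 2L) return(tokens)
  tab <- tabulate(tokens)
  if (2L * max(tab) > n + 1L) {
    abort("Adjacency constraint unsatisfiable: one type holds more than half the tokens.")
  }
  s <- sample(tokens)
  for (sweep in seq_len(max_sweeps)) {
    bad <- which(s[-1L] == s[-n]) + 1L
    if (length(bad) == 0L) return(s)
    for (i in bad) {
      if (s[i] != s[i - 1L]) next  # already repaired by an earlier swap
      a <- s[i]
      for (try in 1:1000) {
        j <- sample.int(n, 1L)
        if (abs(j - i) <= 1L) next
        b <- s[j]
        if (b == a) next
        # after swap: position i holds b, position j holds a
        if (s[i - 1L] == b || (i < n && s[i + 1L] == b)) next
        if ((j > 1L && s[j - 1L] == a) || (j < n && s[j + 1L] == a)) next
        s[i] <- b
        s[j] <- a
        break
      }
    }
  }
  arrange_greedy(tokens)
}

# Draw shifted-Poisson sentence lengths covering `total` tokens exactly;
# trailing remainder shorter than 2 words is merged into the last sentence.
draw_sentence_lengths <- function(total, sentlen_mean) {
  lens <- integer(0)
  got <- 0L
  while (got < total) {
    chunk <- rpois(max(16L, ceiling((total - got) / sentlen_mean)), sentlen_mean - 2) + 2L
    lens <- c(lens, chunk)
    got <- got + sum(chunk)
  }
  cum <- cumsum(lens)
  k <- which(cum >= total)[1]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (cum[k] - total)  # trim the last sentence to fit
  if (lens[k] < 2L) {
    if (k == 1L) abort("Token total too small for a two-word sentence.")
    lens[k - 1L] <- lens[k - 1L] + lens[k]
    lens <- lens[-k]
  }
  lens
}

# Assemble the sentence tibble (words, syllable stream, gold gaps) from a
# token stream and per-sentence word counts.
cut_into_sentences <- function(stream, sent_lens, lexicon) {
  word_len <- lexicon$length
  word_syl <- lexicon$syllables
  ends <- cumsum(sent_lens)
  starts <- ends - sent_lens + 1L
  words <- lapply(seq_along(sent_lens), function(i) stream[starts[i]:ends[i]])
  lens <- lapply(words, function(w) word_len[w])
  tibble::tibble(
    sentence_id = seq_along(words),
    words = words,
    syllables = lapply(words, function(w) unlist(word_syl[w], use.names = FALSE)),
    n_words = lengths(words),
    n_syllables = vapply(lens, sum, 0L),
    gold_gaps = lapply(lens, function(l) if (length(l) > 1L) cumsum(l)[-length(l)] else integer(0))
  )
}

#' Generate the training corpus
#'
#' Realizes the lexicon's token counts as a single stream with no word
#' repeated immediately after itself (enforced across the whole stream,
#' including across sentence boundaries), then cuts the stream into
#' sentences whose lengths in words follow a shifted Poisson,
#' `Poisson(sentlen_mean - 2) + 2`, so every sentence has at least two
#' words; the final sentence is trimmed (or merged into its predecessor)
#' so the token total is exact.
#'
#' In the default exact-count mode the realized per-type counts equal the
#' allocation exactly; `exact_counts = FALSE` instead samples tokens i.i.d.
#' with probabilities proportional to the allocation.
#'
#' @param lexicon Lexicon tibble from [build_lexicon()].
#' @param sentlen_mean Mean sentence length in words (>= 2).
#' @param seed Integer seed.
#' @param exact_counts Realize the allocation exactly (default) or sample
#'   tokens i.i.d. multinomially.
#' @return A corpus tibble: one row per sentence, columns `sentence_id`,
#'   `words` (list of lexicon ranks), `syllables` (list of syllable labels),
#'   `n_words`, `n_syllables`, `gold_gaps` (list of boundary gap indices;
#'   gap g lies between syllables g and g+1). Attributes `role`,
#'   `token_total`, `seed`.
#' @export
generate_corpus <- function(lexicon, sentlen_mean = 4, seed = 1L, exact_counts = TRUE) {
  assert_lexicon(lexicon)
  if (sentlen_mean < 2) abort("`sentlen_mean` must be >= 2.")
  total <- sum(lexicon$frequency)
  with_substream(substream_seed(seed, "corpus"), {
    if (exact_counts) {
      stream <- arrange_no_repeat(rep.int(lexicon$rank, lexicon$frequency))
    } else {
      stream <- sample(lexicon$rank, total, replace = TRUE, prob = lexicon$frequency)
      repeat {
        bad <- which(stream[-1L] == stream[-total]) + 1L
        if (length(bad) == 0L) break
        stream[bad] <- sample(lexicon$rank, length(bad), replace = TRUE,
                              prob = lexicon$frequency)
      }
    }
    sent_lens <- draw_sentence_lengths(total, sentlen_mean)
    out <- cut_into_sentences(stream, sent_lens, lexicon)
  })
  attr(out, "role") <- "training"
  attr(out, "token_total") <- total
  attr(out, "seed") <- seed
  out
}

# One i.i.d. sentence: length ~ Poisson(mean-2)+2, words sampled by frequency
# with no immediate repetition.
sample_sentence <- function(lexicon, sentlen_mean) {
  L <- rpois(1L, sentlen_mean - 2) + 2L
  w <- integer(L)
  for (i in seq_len(L)) {
    repeat {
      cand <- sample(lexicon$rank, 1L, prob = lexicon$frequency)
      if (i == 1L || cand != w[i - 1L]) break
    }
    w[i] <- cand
  }
  w
}

#' Generate a novel-sentence test block
#'
#' Samples sentences by the same process as training (type probabilities
#' proportional to the allocation, shifted-Poisson lengths, no immediate
#' repetition) and keeps only sentences whose word sequence never occurred
#' in training. With the default configuration, 100 sentences average about
#' 400 word tokens.
#'
#' @param lexicon Lexicon tibble.
#' @param training Training corpus the block must be novel with respect to.
#' @param n_sentences Number of novel sentences to emit.
#' @param sentlen_mean Mean sentence length in words.
#' @param seed Integer seed.
#' @param max_tries Sampling budget per emitted sentence.
#' @return A corpus tibble with attribute `role = "test"`.
#' @export
generate_test_block <- function(lexicon, training, n_sentences = 100L,
                                sentlen_mean = 4, seed = 1L, max_tries = 1000L) {
  assert_lexicon(lexicon)
  assert_corpus(training, "training")
  n_sentences <- assert_count(n_sentences, "n_sentences", min = 0L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (key in sentence_key(training$words)) assign(key, TRUE, envir = seen)
  sents <- vector("list", n_sentences)
  with_substream(substream_seed(seed, "test_block"), {
    for (i in seq_len(n_sentences)) {
      tries <- 0L
      repeat {
        w <- sample_sentence(lexicon, sentlen_mean)
        key <- paste(w, collapse = " ")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)  # test sentences also pairwise distinct
          sents[[i]] <- w
          break
        }
        tries <- tries + 1L
        if (tries >= max_tries) abort("Could not find a novel sentence within the retry budget.")
      }
    }
  })
  if (n_sentences == 0L) {
    out <- cut_into_sentences(integer(0), integer(0), lexicon)
  } else {
    out <- cut_into_sentences(unlist(sents), lengths(sents), lexicon)
  }
  attr(out, "role") <- "test"
  attr(out, "token_total") <- sum(out$n_words)
  attr(out, "seed") <- seed
  out
}

#' Generate a complete participant language
#'
#' Convenience wrapper chaining inventory, allocation, lexicon, training
#' corpus and novel test block under one master seed with named substreams.
#'
#' @param n_types,total_tokens,floor Zipf allocation parameters.
#' @param phonology Phoneme lists; defaults to the 24 x 14 inventory.
#' @param length_mean,sentlen_mean Word / sentence length means.
#' @param n_test_sentences Novel sentences in the test block.
#' @param seed Master seed.
#' @param exact_counts Passed to [generate_corpus()].
#' @return A list with elements `inventory`, `allocation`, `lexicon`,
#'   `training`, `test`, `seed`.
#' @export
generate_language <- function(n_types = 1000L, total_tokens = 60000L, floor = 10L,
                              phonology = default_phonology(),
                              length_mean = 3, sentlen_mean = 4,
                              n_test_sentences = 100L, seed = 1L,
                              exact_counts = TRUE) {
  inventory <- build_syllable_inventory(phonology)
  allocation <- allocate_zipf_counts(n_types, total_tokens, floor)
  lexicon <- build_lexicon(inventory, allocation, length_mean,
                           seed = substream_seed(seed, "lang.lexicon"))
  training <- generate_corpus(lexicon, sentlen_mean,
                              seed = substream_seed(seed, "lang.training"),
                              exact_counts = exact_counts)
  test <- generate_test_block(lexicon, training, n_test_sentences, sentlen_mean,
                              seed = substream_seed(seed, "lang.test"))
  list(inventory = inventory, allocation = allocation, lexicon = lexicon,
       training = training, test = test, seed = seed)
}
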