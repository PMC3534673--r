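# Synthetic participants: noisy boundary oracle, transitional-probability
# segmenter (and its untrained yoked-control variant), a frequency-chunk
# parser, a degenerate fixed-period responder, and the 2AFC responder.

new_response <- function(test, gaps, participant, condition) {
  tibble::tibble(
    participant = participant,
    condition = condition,
    sentence_id = test$sentence_id,
    n_syllables = test$n_syllables,
    gaps = gaps
  )
}

#' Noisy-oracle segmenter
#'
#' A controllable stand-in for a trained participant: marks each true
#' boundary gap with probability `hit_rate` and each word-internal gap with
#' probability `false_alarm_rate`, independently across gaps. Its empirical
#' hit and false-alarm rates therefore converge to the parameters, making it
#' the canonical harness for the scoring and inference stages.
#'
#' @param test Test corpus tibble.
#' @param hit_rate,false_alarm_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @param participant,condition Labels carried through to scoring.
#' @return A response tibble: `participant`, `condition`, `sentence_id`,
#'   `n_syllables`, and list-column `gaps` of marked gap indices.
#' @export
oracle_noisy_segmenter <- function(test, hit_rate = 0.6, false_alarm_rate = 0.05,
                                   seed = 1L, participant = "oracle",
                                   condition = "trained") {
  assert_corpus(test, "test")
  if (hit_rate < 0 || hit_rate > 1 || false_alarm_rate < 0 || false_alarm_rate > 1) {
    abort("`hit_rate` and `false_alarm_rate` must lie in [0, 1].")
  }
  gaps <- with_substream(substream_seed(seed, "oracle"), {
    mapply(function(L, gold) {
      g <- seq_len(max(L - 1L, 0L))
      is_b <- g %in% gold
      p <- ifelse(is_b, hit_rate, false_alarm_rate)
      g[runif(length(g)) < p]
    }, test$n_syllables, test$gold_gaps, SIMPLIFY = FALSE)
  })
  new_response(test, gaps, participant, condition)
}

#' Estimate syllable transitional probabilities
#'
#' Accumulates syllable bigram counts within sentences only (the
#' inter-sentence pause breaks bigrams) and normalizes each predecessor's
#' row: `P(s2 | s1) = count(s1 s2) / count(s1 .)`.
#'
#' @param corpus Corpus tibble (training material).
#' @return A tibble with columns `s1`, `s2`, `n`, `p`; attribute
#'   `s1_totals` holds per-predecessor bigram totals.
#' @export
estimate_tp <- function(corpus) {
  assert_corpus(corpus)
  if (nrow(corpus) == 0L) abort("Cannot estimate transitional probabilities from an empty corpus.")
  s1 <- unlist(lapply(corpus$syllables, function(s) s[-length(s)]), use.names = FALSE)
  s2 <- unlist(lapply(corpus$syllables, function(s) s[-1L]), use.names = FALSE)
  out <- dplyr::count(tibble::tibble(s1 = s1, s2 = s2), .data$s1, .data$s2, name = "n")
  out <- dplyr::mutate(dplyr::group_by(out, .data$s1), p = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  attr(out, "s1_totals") <- tapply(out$n, out$s1, sum)
  out
}

# fast lookup closure over a TP table; unseen bigrams have probability 0
tp_lookup <- function(table) {
  probs <- setNames(table$p, paste(table$s1, table$s2, sep = "\r"))
  function(a, b) {
    p <- probs[paste(a, b, sep = "\r")]
    ifelse(is.na(p), 0, unname(p))
  }
}

#' Transitional-probability segmenter
#'
#' Marks a gap wherever the transitional probability of the following
#' syllable given the preceding one falls below `tp_threshold`. Bigrams
#' never seen in training are treated as probability 0 (always marked): a
#' novel juncture is taken as evidence of a boundary.
#'
#' @param test Test corpus tibble.
#' @param table TP table from [estimate_tp()].
#' @param tp_threshold Boundary threshold on P(next | prev).
#' @param participant,condition Labels carried through to scoring.
#' @return A response tibble (see [oracle_noisy_segmenter()]).
#' @export
tp_segmenter <- function(test, table, tp_threshold = 0.05,
                         participant = "tp", condition = "trained") {
  assert_corpus(test, "test")
  look <- tp_lookup(table)
  gaps <- lapply(test$syllables, function(s) {
    L <- length(s)
    if (L < 2L) return(integer(0))
    which(look(s[-L], s[-1L]) < tp_threshold)
  })
  new_response(test, gaps, participant, condition)
}

#' Yoked-control segmenter
#'
#' Models a participant who received the identical test but no training:
#' transitional probabilities are estimated from the test block alone, then
#' the TP segmenter is applied. Captures what is learnable from the test
#' session itself (mostly the highest-frequency words).
#'
#' @inheritParams tp_segmenter
#' @return A response tibble.
#' @export
yoked_control_segmenter <- function(test, tp_threshold = 0.05,
                                    participant = "yoked", condition = "yoked-control") {
  assert_corpus(test, "test")
  if (nrow(test) == 0L) {
    return(new_response(test, list(), participant, condition))
  }
  tp_segmenter(test, estimate_tp(test), tp_threshold,
               participant = participant, condition = condition)
}

#' Fixed-period segmenter
#'
#' Reproduces the degenerate strategy of placing a boundary every `period`
#' syllables without variation in every sentence — the response pattern
#' that is uninterpretable and grounds for exclusion.
#'
#' @param test Test corpus tibble.
#' @param period Lattice period in syllables (>= 1).
#' @param participant,condition Labels.
#' @return A response tibble.
#' @export
periodic_segmenter <- function(test, period = 2L, participant = "periodic",
                               condition = "degenerate") {
  assert_corpus(test, "test")
  period <- assert_count(period, "period", min = 1L)
  gaps <- lapply(test$n_syllables, function(L) {
    if (L - 1L < period) integer(0) else seq.int(period, L - 1L, by = period)
  })
  new_response(test, gaps, participant, condition)
}

#' Frequency-chunk segmenter
#'
#' A lexicon-based alternative mechanism: collects the `n_chunks` most
#' frequent attested syllable n-grams (up to `max_len` syllables) from the
#' training corpus, then greedily parses each test sentence leftmost-longest
#' with that chunk inventory, placing boundaries at parse-unit edges.
#' Unmatched positions are consumed one syllable at a time.
#'
#' @param test Test corpus tibble.
#' @param training Training corpus the chunk inventory is built from.
#' @param n_chunks Chunk inventory size.
#' @param max_len Maximum chunk length in syllables.
#' @param participant,condition Labels.
#' @return A response tibble.
#' @export
chunk_segmenter <- function(test, training, n_chunks = 500L, max_len = 5L,
                            participant = "chunk", condition = "trained") {
  assert_corpus(test, "test")
  assert_corpus(training, "training")
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (s in training$syllables) {
    L <- length(s)
    for (k in seq_len(min(max_len, L))) {
      for (i in seq_len(L - k + 1L)) {
        key <- paste(s[i:(i + k - 1L)], collapse = " ")
        assign(key, get0(key, envir = counts, ifnotfound = 0L) + 1L, envir = counts)
      }
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], 0L)
  top <- keys[order(-freq, keys)][seq_len(min(n_chunks, length(keys)))]
  chunk_set <- new.env(hash = TRUE, parent = emptyenv())
  for (k in top) assign(k, TRUE, envir = chunk_set)
  gaps <- lapply(test$syllables, function(s) {
    L <- length(s)
    edges <- integer(0)
    i <- 1L
    while (i <= L) {
      len <- 1L
      for (k in rev(seq_len(min(max_len, L - i + 1L)))) {  # leftmost-longest
        if (exists(paste(s[i:(i + k - 1L)], collapse = " "), envir = chunk_set,
                   inherits = FALSE)) { len <- k; break }
      }
      i <- i + len
      if (i <= L) edges <- c(edges, i - 1L)
    }
    edges
  })
  new_response(test, gaps, participant, condition)
}

#' Simulate 2AFC choices with log-frequency-dependent accuracy
#'
#' The generative inverse of the half-logit psychometric model: the target
#' is chosen with probability `0.5 + 0.5 * plogis(beta0 + beta1 * log(f))`,
#' where `f` is the target's training token frequency, independently across
#' trials. Accuracy is floored at chance (0.5) by construction.
#'
#' @param trials Trial tibble from [build_twoafc_trials()].
#' @param beta0,beta1 Intercept and log-frequency slope on the logit scale.
#' @param seed Integer seed.
#' @param participant Label.
#' @return The trial tibble with added columns `participant`, `p_correct`,
#'   `chose_target`.
#' @export
twoafc_responder <- function(trials, beta0 = -4, beta1 = 1, seed = 1L,
                             participant = "sim") {
  stopifnot(is.data.frame(trials), "target_freq" %in% names(trials))
  p <- 0.5 + 0.5 * plogis(beta0 + beta1 * log(trials$target_freq))
  chose <- with_substream(substream_seed(seed, "twoafc"),
                          runif(nrow(trials)) < p)
  dplyr::mutate(trials, participant = participant, p_correct = p, chose_target = chose)
}

#' Serialize segmentation responses as CSV lines
#'
#' One line per sentence: participant, sentence index, and the sorted
#' predicted gap indices (semicolon-separated within the field).
#'
#' @param response Response tibble.
#' @param path Optional file path; if omitted the lines are returned.
#' @return Character vector of CSV lines (invisibly when written).
#' @export
write_response_csv <- function(response, path = NULL) {
  assert_response(response)
  lines <- c("participant,condition,sentence_id,gaps",
             sprintf("%s,%s,%d,%s", response$participant, response$condition,
                     response$sentence_id,
                     vapply(response$gaps, function(g) paste(sort(g), collapse = ";"), "")))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
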