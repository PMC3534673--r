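# Scoring against gold boundaries, within-sentence permutation nulls,
# location-level frequency analysis, and degenerate-strategy detection.

#' Score a segmentation response against gold boundaries
#'
#' A hit is a marked gap where a word boundary exists, a miss an unmarked
#' boundary, and a false alarm a marked word-internal gap. Precision is
#' hits/(hits+false alarms), recall hits/(hits+misses), and the F-score
#' their harmonic mean. Counts are pooled over sentences before computing
#' the ratios (micro-average); a 0/0 ratio is defined as 0.
#'
#' @param response Response tibble.
#' @param gold Corpus tibble with the gold `gold_gaps`.
#' @param by_sentence Also return per-sentence rows?
#' @return A tibble of scores; one corpus-level row (level `"corpus"`), plus
#'   per-sentence rows when requested.
#' @export
#' @examples
#' lang <- generate_language(n_types = 20, total_tokens = 400, floor = 2,
#'                           n_test_sentences = 10, seed = 7)
#' resp <- oracle_noisy_segmenter(lang$test, 1, 0)
#' score_segmentation(resp, lang$test)$f_score # 1
score_segmentation <- function(response, gold, by_sentence = FALSE) {
  assert_response(response)
  assert_corpus(gold, "gold")
  if (nrow(response) != nrow(gold) ||
      !all(response$n_syllables == gold$n_syllables)) {
    abort("Response and gold cover different sentences (length mismatch).")
  }
  h <- mapply(function(p, g) length(intersect(p, g)), response$gaps, gold$gold_gaps)
  m <- lengths(gold$gold_gaps) - h
  fa <- lengths(response$gaps) - h
  prf <- function(hits, miss, falarm) {
    precision <- ifelse(hits + falarm > 0, hits / (hits + falarm), 0)
    recall <- ifelse(hits + miss > 0, hits / (hits + miss), 0)
    f <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
    tibble::tibble(hits = hits, misses = miss, false_alarms = falarm,
                   precision = precision, recall = recall, f_score = f)
  }
  out <- dplyr::mutate(prf(sum(h), sum(m), sum(fa)),
                       level = "corpus", sentence_id = NA_integer_,
                       participant = response$participant[1] %||% NA_character_,
                       condition = response$condition[1] %||% NA_character_)
  if (by_sentence) {
    per <- dplyr::mutate(prf(h, m, fa), level = "sentence",
                         sentence_id = response$sentence_id,
                         participant = response$participant,
                         condition = response$condition)
    out <- dplyr::bind_rows(out, per)
  }
  out
}

#' Classify every gap decision by boundary status and word frequency
#'
#' Produces one record per gap per sentence. A gap at a word boundary is
#' labelled with the higher of the two adjacent words' training frequencies;
#' a word-internal gap with the frequency of its containing word. `correct`
#' is TRUE when the gap was marked if and only if a boundary exists there.
#'
#' @param response Response tibble.
#' @param gold Corpus tibble.
#' @param lexicon Lexicon tibble supplying per-rank frequencies.
#' @return A tibble with columns `participant`, `condition`, `sentence_id`,
#'   `gap`, `is_boundary`, `marked`, `correct`, `freq_label`, `log_freq`.
#' @export
classify_locations <- function(response, gold, lexicon) {
  assert_response(response)
  assert_corpus(gold, "gold")
  assert_lexicon(lexicon)
  freq <- lexicon$frequency[order(lexicon$rank)]
  rows <- mapply(function(words, L, marked_gaps) {
    if (L < 2L) return(NULL)
    wlen <- lexicon$length[match(words, lexicon$rank)]
    word_of <- rep.int(seq_along(words), wlen)  # word index per syllable
    g <- seq_len(L - 1L)
    wl <- word_of[g]
    wr <- word_of[g + 1L]
    is_b <- wl != wr
    fl <- freq[words[wl]]
    fr <- freq[words[wr]]
    tibble::tibble(gap = g, is_boundary = is_b,
                   marked = g %in% marked_gaps,
                   freq_label = ifelse(is_b, pmax(fl, fr), fl))
  }, gold$words, gold$n_syllables, response$gaps, SIMPLIFY = FALSE)
  n_per <- vapply(rows, function(r) if (is.null(r)) 0L else nrow(r), 0L)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
                       correct = .data$marked == .data$is_boundary,
                       log_freq = log(.data$freq_label))
  dplyr::bind_cols(
    tibble::tibble(participant = rep(response$participant, n_per),
                   condition = rep(response$condition, n_per),
                   sentence_id = rep(response$sentence_id, n_per)),
    out
  )
}

#' Bin location decisions by log frequency
#'
#' Equal-width bins on the natural log of the frequency label, split by
#' boundary status, with the proportion correct and an equal-tailed 95%
#' Beta-posterior interval per cell (Jeffreys prior by default) — the
#' figure-ready accuracy-by-frequency table.
#'
#' @param decisions Output of [classify_locations()].
#' @param n_bins Number of equal-width bins on log frequency.
#' @param prior Beta prior `(a, b)`; default Jeffreys `(1/2, 1/2)`.
#' @return A tibble with one row per bin x boundary status: `bin`,
#'   `log_freq_mid`, `is_boundary`, `n`, `n_correct`, `prop_correct`,
#'   `ci_low`, `ci_high`.
#' @export
bin_by_log_frequency <- function(decisions, n_bins = 8L, prior = c(0.5, 0.5)) {
  stopifnot(is.data.frame(decisions), nrow(decisions) > 0L)
  rng <- range(decisions$log_freq)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- decisions |>
    dplyr::mutate(bin = cut(.data$log_freq, breaks, include.lowest = TRUE,
                            labels = FALSE)) |>
    dplyr::group_by(.data$bin, .data$is_boundary) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(log_freq_mid = mids[.data$bin],
                  prop_correct = .data$n_correct / .data$n)
  ci <- beta_binomial_interval(out$n_correct, out$n, prior = prior)
  dplyr::bind_cols(out, ci[, c("low", "high")] |>
                     stats::setNames(c("ci_low", "ci_high")))
}

#' Draw one uniform placement of m marks among G gaps
#'
#' The elementary shuffle behind the permutation baseline: a uniformly
#' random size-`m` subset of the `G` within-sentence gaps.
#'
#' @param G Number of gaps in the sentence.
#' @param m Number of marks to place.
#' @return Sorted integer vector of `m` gap indices.
#' @export
permute_gaps <- function(G, m) {
  if (m > G) abort("Cannot place more marks than gaps.")
  sort(sample.int(G, m))
}

#' Permutation-null chance baseline for the F-score
#'
#' Shuffles the responder's own boundary marks within each sentence,
#' keeping each sentence's number of marks constant, and recomputes the
#' corpus-level F-score for each of `n_reps` simulated segmentations. With
#' micro-averaged counts, F = 2H/(M+K) where H is the total hit count and M,
#' K the total marked and true boundaries, so each replicate's F follows
#' from per-sentence hit counts, which under a uniform redraw of m marks
#' among G gaps are hypergeometric (k true boundaries among G). The engine
#' draws them as such; [permute_gaps()] exposes the equivalent explicit
#' shuffle.
#'
#' Reports the empirical 95% interval of permuted F and a one-sided p-value
#' for the observed F with the add-one correction (observed counted among
#' the samples).
#'
#' @param response Response tibble.
#' @param gold Corpus tibble.
#' @param n_reps Number of simulated segmentations per sentence.
#' @param seed Integer seed.
#' @return An object of class `seglab_permnull`: list with `observed_f`,
#'   `f_samples`, `ci_low`, `ci_high`, `p_value`, `n_reps`, and a
#'   per-sentence tibble `sentences` (m, k, G).
#' @export
permutation_baseline <- function(response, gold, n_reps = 10000L, seed = 1L) {
  assert_response(response)
  assert_corpus(gold, "gold")
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  m <- lengths(response$gaps)
  k <- lengths(gold$gold_gaps)
  G <- pmax(gold$n_syllables - 1L, 0L)
  if (any(m > G)) abort("A sentence has more marks than gaps.")
  M <- sum(m); K <- sum(k)
  hits <- with_substream(substream_seed(seed, "permutation"), {
    tot <- numeric(n_reps)
    for (i in seq_along(m)) {
      if (m[i] == 0L || k[i] == 0L) next
      tot <- tot + rhyper(n_reps, k[i], G[i] - k[i], m[i])
    }
    tot
  })
  f_samples <- if (M + K > 0) 2 * hits / (M + K) else rep(0, n_reps)
  obs <- score_segmentation(response, gold)$f_score[1]
  ci <- unname(quantile(f_samples, c(0.025, 0.975)))
  structure(list(
    observed_f = obs,
    f_samples = f_samples,
    ci_low = ci[1], ci_high = ci[2],
    p_value = (sum(f_samples >= obs) + 1) / (n_reps + 1),
    n_reps = n_reps,
    sentences = tibble::tibble(sentence_id = gold$sentence_id, m = m, k = k, G = G)
  ), class = "seglab_permnull")
}

#' @export
print.seglab_permnull <- function(x, ...) {
  cat(sprintf(
    "Permutation baseline (%d reps)\n  observed F = %.3f\n  null 95%% CI [%.3f, %.3f]\n  one-sided p = %.4g\n",
    x$n_reps, x$observed_f, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @export
#' @method glance seglab_permnull
glance.seglab_permnull <- function(x, ...) {
  tibble::tibble(observed_f = x$observed_f, ci_low = x$ci_low,
                 ci_high = x$ci_high, p_value = x$p_value, n_reps = x$n_reps)
}

#' Detect a degenerate fixed-period response strategy
#'
#' Flags a response whose marks form an exact fixed-period lattice (gaps p,
#' 2p, 3p, ... in every sentence, for some period p) — such a response
#' carries no item information and is uninterpretable, so it is excluded
#' from analysis. A response with no marks anywhere is flagged with period
#' infinity.
#'
#' @param response Response tibble.
#' @return A one-row tibble: `flagged` (logical), `period` (numeric; `Inf`
#'   for the all-empty response, `NA` when not flagged).
#' @export
detect_degenerate_strategy <- function(response) {
  assert_response(response)
  if (nrow(response) == 0L) abort("Empty response table.")
  nonempty <- which(lengths(response$gaps) > 0L)
  if (length(nonempty) == 0L) {
    return(tibble::tibble(flagged = TRUE, period = Inf))
  }
  p <- min(response$gaps[[nonempty[1]]])
  lattice <- function(L) if (L - 1L >= p) seq.int(p, L - 1L, by = p) else integer(0)
  ok <- all(mapply(function(g, L) identical(as.integer(sort(g)), as.integer(lattice(L))),
                   response$gaps, response$n_syllables))
  tibble::tibble(flagged = ok, period = if (ok) as.numeric(p) else NA_real_)
}
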