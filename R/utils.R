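# Internal helpers: seeding substreams, input validation.

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a stage label (and optional unit index, e.g. a
#' participant number) to a deterministic 31-bit seed, so every stochastic
#' stage of a pipeline can be re-run in isolation.
#'
#' @param master Integer master seed.
#' @param stage Character stage label, e.g. `"lexicon"`.
#' @param unit Optional non-negative integer (participant / replicate index).
#' @return A single integer in `[0, 2^31)`.
#' @export
substream_seed <- function(master, stage, unit = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer((h * 131 + as.double(unit)) %% 2147483647)
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
with_substream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_corpus <- function(x, name = "corpus") {
  need <- c("sentence_id", "words", "syllables", "n_words", "n_syllables", "gold_gaps")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a seglab corpus (see `generate_corpus()`).", name))
  }
  invisible(x)
}

assert_response <- function(x, name = "response") {
  need <- c("participant", "condition", "sentence_id", "n_syllables", "gaps")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a segmentation response (see `oracle_noisy_segmenter()`).", name))
  }
  invisible(x)
}

assert_lexicon <- function(x, name = "lexicon") {
  need <- c("rank", "form", "length", "frequency", "syllables")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a seglab lexicon (see `build_lexicon()`).", name))
  }
  invisible(x)
}

# key for a word-rank sequence, used for novelty checks
sentence_key <- function(words) vapply(words, paste, "", collapse = " ")
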