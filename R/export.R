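# Serialization: orthographic glosses, gold boundary files, MBROLA-style
# .pho timing tracks, and the on-disk language bundle.

#' Render a corpus as orthographically glossed lines
#'
#' One sentence per line, syllables space-separated, with no boundary marks
#' — the format participants see on screen ("go lah bu pa doh ti"). With
#' `reveal_boundaries`, the gold word boundaries are spliced in as a
#' delimiter token (for debugging and gold export only).
#'
#' @param corpus Corpus tibble.
#' @param reveal_boundaries Mark word boundaries with `delimiter`?
#' @param delimiter Boundary marker used when revealing.
#' @return Character vector, one element per sentence.
#' @export
corpus_to_gloss <- function(corpus, reveal_boundaries = FALSE, delimiter = "|") {
  assert_corpus(corpus)
  if (!reveal_boundaries) {
    return(vapply(corpus$syllables, paste, "", collapse = " "))
  }
  mapply(function(syl, gaps) {
    pieces <- character(0)
    prev <- 0L
    for (g in c(gaps, length(syl))) {
      pieces <- c(pieces, paste(syl[(prev + 1L):g], collapse = " "))
      prev <- g
    }
    paste(pieces, collapse = paste0(" ", delimiter, " "))
  }, corpus$syllables, corpus$gold_gaps, USE.NAMES = FALSE)
}

#' Render gold boundaries as text lines
#'
#' One line per sentence: the sorted gap indices, comma-separated (empty
#' line for a sentence with a single word).
#'
#' @param corpus Corpus tibble.
#' @return Character vector, one element per sentence.
#' @export
corpus_to_gold <- function(corpus) {
  assert_corpus(corpus)
  vapply(corpus$gold_gaps, function(g) paste(sort(g), collapse = ","), "")
}

#' Reconstruct a corpus from gloss and gold lines
#'
#' Inverse of [corpus_to_gloss()] + [corpus_to_gold()]: recovers the
#' syllable streams and boundary gap sets exactly; if a lexicon is supplied,
#' word forms are mapped back to lexicon ranks.
#'
#' @param gloss Character vector of glossed sentences (no boundary marks).
#' @param gold Character vector of comma-separated gap indices.
#' @param lexicon Optional lexicon for rank lookup.
#' @return A corpus tibble; `words` holds ranks when a lexicon is given,
#'   otherwise `NA`.
#' @export
read_gloss <- function(gloss, gold, lexicon = NULL) {
  if (length(gloss) != length(gold)) abort("`gloss` and `gold` must have equal length.")
  syl <- strsplit(gloss, " ", fixed = TRUE)
  gaps <- lapply(gold, function(x) {
    if (!nzchar(x)) integer(0) else as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  rank_of <- NULL
  if (!is.null(lexicon)) {
    assert_lexicon(lexicon)
    rank_of <- setNames(lexicon$rank, lexicon$form)
  }
  words <- mapply(function(s, g) {
    bounds <- c(0L, g, length(s))
    forms <- vapply(seq_len(length(bounds) - 1L), function(i) {
      paste(s[(bounds[i] + 1L):bounds[i + 1L]], collapse = " ")
    }, "")
    if (is.null(rank_of)) rep(NA_integer_, length(forms)) else unname(rank_of[forms])
  }, syl, gaps, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  tibble::tibble(
    sentence_id = seq_along(syl),
    words = words,
    syllables = syl,
    n_words = lengths(gaps) + 1L,
    n_syllables = lengths(syl),
    gold_gaps = gaps
  )
}

#' Export a corpus as MBROLA-style .pho timing batches
#'
#' Each syllable is split into its consonant and vowel phoneme, 125 ms each
#' (250 ms per syllable total), at a constant pitch anchor (100 Hz by
#' default); each sentence is followed by a 200 ms silence line (`_ 200`).
#' Nothing in the track marks word boundaries. Batches are chunked to about
#' `batch_minutes` of audio, never splitting a sentence.
#'
#' @param corpus Corpus tibble.
#' @param inventory Syllable inventory tibble mapping each syllable to its
#'   consonant and vowel.
#' @param syllable_ms Syllable duration, milliseconds.
#' @param pause_ms Inter-sentence silence, milliseconds.
#' @param pitch_hz Constant fundamental frequency.
#' @param batch_minutes Approximate batch duration in minutes.
#' @param path If non-NULL, directory where `batch_NNN.pho` files are written.
#' @return Invisibly (if `path` given) or visibly, a list of character
#'   vectors, one per batch; attribute `durations_ms` holds total batch
#'   durations (voiced + pauses).
#' @export
corpus_to_pho <- function(corpus, inventory, syllable_ms = 250, pause_ms = 200,
                          pitch_hz = 100, batch_minutes = 5, path = NULL) {
  assert_corpus(corpus)
  stopifnot(all(c("syllable", "consonant", "vowel") %in% names(inventory)))
  if (nrow(corpus) == 0L) {
    out <- list()
    attr(out, "durations_ms") <- numeric(0)
    return(out)
  }
  cons <- setNames(inventory$consonant, inventory$syllable)
  vows <- setNames(inventory$vowel, inventory$syllable)
  half <- syllable_ms / 2
  sentence_lines <- lapply(corpus$syllables, function(syl) {
    if (anyNA(cons[syl])) {
      abort(sprintf("Unmapped syllable(s): %s",
                    paste(unique(syl[is.na(cons[syl])]), collapse = ", ")))
    }
    ph <- as.vector(rbind(cons[syl], vows[syl]))
    c(sprintf("%s %g 50 %g", ph, half, pitch_hz), sprintf("_ %g", pause_ms))
  })
  sent_ms <- corpus$n_syllables * syllable_ms + pause_ms
  budget <- batch_minutes * 60000
  batch_id <- integer(length(sent_ms))
  cur <- 1L; acc <- 0
  for (i in seq_along(sent_ms)) {
    if (acc > 0 && acc + sent_ms[i] > budget) { cur <- cur + 1L; acc <- 0 }
    batch_id[i] <- cur
    acc <- acc + sent_ms[i]
  }
  batches <- lapply(split(sentence_lines, batch_id),
                    function(b) unlist(b, use.names = FALSE))
  names(batches) <- NULL
  attr(batches, "durations_ms") <- as.numeric(tapply(sent_ms, batch_id, sum))
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(batches)) {
      writeLines(batches[[i]], file.path(path, sprintf("batch_%03d.pho", i)))
    }
    return(invisible(batches))
  }
  batches
}

#' Write a language bundle directory
#'
#' Serializes a generated language as plain text: `lexicon.json` (rank,
#' form, length, frequency), `train.txt` / `test.txt` (glossed, no boundary
#' marks), `gold_train.txt` / `gold.txt` (gap indices), and `config.yaml`.
#'
#' @param language A list as returned by [generate_language()].
#' @param dir Output directory (created if needed).
#' @param config Optional named list echoed to `config.yaml`.
#' @return `dir`, invisibly.
#' @export
write_language_bundle <- function(language, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lex <- language$lexicon[, c("rank", "form", "length", "frequency")]
  jsonlite::write_json(lex, file.path(dir, "lexicon.json"), dataframe = "rows")
  writeLines(corpus_to_gloss(language$training), file.path(dir, "train.txt"))
  writeLines(corpus_to_gold(language$training), file.path(dir, "gold_train.txt"))
  writeLines(corpus_to_gloss(language$test), file.path(dir, "test.txt"))
  writeLines(corpus_to_gold(language$test), file.path(dir, "gold.txt"))
  if (is.null(config)) config <- list(seed = language$seed)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a language bundle directory
#'
#' @param dir Bundle directory written by [write_language_bundle()].
#' @return A list with `lexicon` (ranks/forms/lengths/frequencies plus
#'   reconstructed syllable lists), `training`, `test`, `config`.
#' @export
read_language_bundle <- function(dir) {
  lex <- jsonlite::read_json(file.path(dir, "lexicon.json"), simplifyVector = TRUE)
  lex <- tibble::as_tibble(lex)
  lex$syllables <- strsplit(lex$form, " ", fixed = TRUE)
  training <- read_gloss(readLines(file.path(dir, "train.txt")),
                         readLines(file.path(dir, "gold_train.txt")), lexicon = lex)
  test <- read_gloss(readLines(file.path(dir, "test.txt")),
                     readLines(file.path(dir, "gold.txt")), lexicon = lex)
  attr(training, "role") <- "training"
  attr(test, "role") <- "test"
  list(lexicon = lex, training = training, test = test,
       config = yaml::read_yaml(file.path(dir, "config.yaml")))
}
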