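# End-to-end experiment simulation: N participant languages, two interim
# segmentation tests plus yoked controls, scoring with permutation
# baselines, the location-level frequency analysis, and the 2AFC retention
# test with half-logit fits.

#' Build an experiment configuration
#'
#' Defaults reproduce the study conditions: four participants, each with a
#' unique language of 1000 word types and 60,000 tokens under a floored
#' Zipfian allocation (min 10), a 336-syllable CV inventory, shifted-Poisson
#' word lengths (mean 3) and sentence lengths (mean 4 words), two interim
#' tests of 100 novel sentences each, 10,000-replicate permutation
#' baselines, and a 64-trial 2AFC with frequency cutoff 1000.
#'
#' @param n_participants Number of trained participants (each yoked to one
#'   untrained control).
#' @param n_types,total_tokens,zipf_floor Language size parameters.
#' @param length_mean,sentlen_mean Word / sentence length means.
#' @param n_test_sentences Sentences per interim test block.
#' @param n_permutations Permutation replicates per baseline.
#' @param n_twoafc_trials,freq_cutoff 2AFC test parameters.
#' @param learner Trained-learner mechanism: `"tp"`, `"oracle"`, or `"chunk"`.
#' @param tp_threshold TP boundary threshold.
#' @param hit_rate,false_alarm_rate Noisy-oracle rates.
#' @param beta0,beta1 2AFC responder coefficients.
#' @param seed Master seed; all stages draw named substreams from it.
#' @return A named list of class `seglab_config`.
#' @export
experiment_config <- function(n_participants = 4L,
                              n_types = 1000L, total_tokens = 60000L,
                              zipf_floor = 10L,
                              length_mean = 3, sentlen_mean = 4,
                              n_test_sentences = 100L,
                              n_permutations = 10000L,
                              n_twoafc_trials = 64L, freq_cutoff = 1000L,
                              learner = c("tp", "oracle", "chunk"),
                              tp_threshold = 0.05,
                              hit_rate = 0.6, false_alarm_rate = 0.05,
                              beta0 = -4, beta1 = 1,
                              seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_types = as.integer(n_types), total_tokens = as.integer(total_tokens),
    zipf_floor = as.integer(zipf_floor),
    length_mean = length_mean, sentlen_mean = sentlen_mean,
    n_test_sentences = as.integer(n_test_sentences),
    n_permutations = as.integer(n_permutations),
    n_twoafc_trials = as.integer(n_twoafc_trials),
    freq_cutoff = as.integer(freq_cutoff),
    learner = match.arg(learner),
    tp_threshold = tp_threshold,
    hit_rate = hit_rate, false_alarm_rate = false_alarm_rate,
    beta0 = beta0, beta1 = beta1,
    seed = as.integer(seed)
  )
  class(cfg) <- c("seglab_config", "list")
  cfg
}

#' Read / write an experiment configuration
#'
#' Round-trips [experiment_config()] through YAML.
#'
#' @param config A `seglab_config` list.
#' @param path YAML file path.
#' @return `read_experiment_config()` returns a `seglab_config`.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

trained_response <- function(cfg, lang, test, participant, seed) {
  switch(cfg$learner,
    tp = tp_segmenter(test, estimate_tp(lang$training), cfg$tp_threshold,
                      participant = participant, condition = "trained"),
    oracle = oracle_noisy_segmenter(test, cfg$hit_rate, cfg$false_alarm_rate,
                                    seed = seed, participant = participant,
                                    condition = "trained"),
    chunk = chunk_segmenter(test, lang$training,
                            participant = participant, condition = "trained")
  )
}

#' Run the full simulated experiment
#'
#' For each participant: generates a unique language, runs two interim
#' segmentation tests (the second on fresh novel sentences, with no further
#' exposure between tests) for the trained learner and a yoked control,
#' scores each response against gold with a within-sentence permutation
#' baseline and a degeneracy check, classifies every gap decision for the
#' frequency analysis, and runs the 2AFC retention test (distractors drawn
#' from the next participant's language) with a half-logit fit. When
#' `out_dir` is given, language bundles, response CSVs and report tables
#' are written there.
#'
#' @param config A `seglab_config` from [experiment_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage progress messages?
#' @return A list of class `seglab_experiment`: `report` (one row per
#'   participant x condition x test with P/R/F, the permutation CI and
#'   p-value, and the degeneracy flag), `decisions` (all location
#'   decisions), `freq_bound` (pooled frequency x boundary model),
#'   `twoafc` (scored trials), `half_logit_fits` (per participant),
#'   `languages`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "seglab_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  n <- config$n_participants
  say("Generating %d participant languages ...", n)
  langs <- lapply(seq_len(n), function(p) {
    generate_language(
      n_types = config$n_types, total_tokens = config$total_tokens,
      floor = config$zipf_floor, length_mean = config$length_mean,
      sentlen_mean = config$sentlen_mean,
      n_test_sentences = config$n_test_sentences,
      seed = substream_seed(config$seed, "language", p)
    )
  })

  report <- list()
  decisions <- list()
  fits <- list()
  twoafc_all <- list()

  for (p in seq_len(n)) {
    lang <- langs[[p]]
    pid <- sprintf("P%d", p)
    say("Participant %s: interim tests ...", pid)
    tests <- list(
      test1 = lang$test,
      test2 = generate_test_block(lang$lexicon, lang$training,
                                  config$n_test_sentences, config$sentlen_mean,
                                  seed = substream_seed(config$seed, "test2", p))
    )
    for (tname in names(tests)) {
      test <- tests[[tname]]
      resp <- list(
        trained = trained_response(config, lang, test, pid,
                                   substream_seed(config$seed, paste0("resp.", tname), p)),
        `yoked-control` = yoked_control_segmenter(test, config$tp_threshold,
                                                  participant = paste0("Y", p))
      )
      for (cond in names(resp)) {
        r <- resp[[cond]]
        sc <- score_segmentation(r, test)
        base <- permutation_baseline(r, test, config$n_permutations,
                                     seed = substream_seed(config$seed,
                                                           paste0("perm.", tname, ".", cond), p))
        deg <- detect_degenerate_strategy(r)
        report[[length(report) + 1L]] <- dplyr::mutate(
          sc[sc$level == "corpus", ],
          test = tname, ci_low = base$ci_low, ci_high = base$ci_high,
          p_value = base$p_value, degenerate = deg$flagged
        )
        if (cond == "trained" && tname == "test1") {
          decisions[[pid]] <- classify_locations(r, test, lang$lexicon)
        }
      }
      if (!is.null(out_dir)) {
        dir.create(file.path(out_dir, pid), showWarnings = FALSE, recursive = TRUE)
        write_response_csv(resp$trained,
                           file.path(out_dir, pid, paste0(tname, "_trained.csv")))
        write_response_csv(resp$`yoked-control`,
                           file.path(out_dir, pid, paste0(tname, "_yoked.csv")))
      }
    }
    say("Participant %s: 2AFC retention test ...", pid)
    lexB <- langs[[if (p == n) 1L else p + 1L]]$lexicon
    trials <- build_twoafc_trials(lang$lexicon, lexB, config$n_twoafc_trials,
                                  config$freq_cutoff,
                                  seed = substream_seed(config$seed, "trials", p))
    choices <- twoafc_responder(trials, config$beta0, config$beta1,
                                seed = substream_seed(config$seed, "choices", p),
                                participant = pid)
    scored <- score_twoafc(trials, choices)
    twoafc_all[[pid]] <- dplyr::mutate(scored, participant = pid)
    fits[[pid]] <- fit_half_logit(scored)
    if (!is.null(out_dir)) {
      write_language_bundle(lang, file.path(out_dir, pid, "language"))
      utils::write.csv(scored, file.path(out_dir, pid, "twoafc.csv"),
                       row.names = FALSE)
    }
  }

  decisions <- dplyr::bind_rows(decisions)
  report <- dplyr::bind_rows(report)
  freq_bound <- fit_freq_bound_model(decisions)
  out <- structure(list(
    report = report, decisions = decisions, freq_bound = freq_bound,
    twoafc = dplyr::bind_rows(twoafc_all), half_logit_fits = fits,
    languages = langs, config = config
  ), class = "seglab_experiment")
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

#' @export
print.seglab_experiment <- function(x, ...) {
  cat(sprintf("Simulated segmentation experiment: %d participants\n",
              x$config$n_participants))
  print(x$report[, c("participant", "condition", "test", "precision", "recall",
                     "f_score", "ci_high", "p_value")], n = Inf)
  invisible(x)
}
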