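# Retention test: 2AFC trial construction with frequency/length-matched
# cross-language distractors, choice scoring, and the half-logit
# accuracy-frequency psychometric fit.

#' Build 2AFC trials with cross-language distractors
#'
#' Targets come from language A's lexicon: every word with training
#' frequency above `freq_cutoff` is included, and the remaining slots are
#' filled by sampling uniformly on the log-frequency range spanned by the
#' lexicon (each draw mapped to the nearest unused word). Each target is
#' paired with a distractor from language B's lexicon of the same syllable
#' length, whose syllables all occur in both languages' inventories and
#' whose form is not the target's, choosing the closest log-frequency match
#' (ties broken at random under the seed); distractors are not reused.
#'
#' @param lexA Target (trained) lexicon.
#' @param lexB Distractor lexicon from another participant's language.
#' @param n_trials Total trials to emit.
#' @param freq_cutoff Frequency above which every word is an obligatory target.
#' @param seed Integer seed.
#' @param log_tol Preferred absolute log-frequency matching tolerance
#'   (soft; the closest candidate is used regardless, the tolerance only
#'   governs the `freq_matched` flag).
#' @return A tibble with one row per trial: target and distractor rank,
#'   form, length and frequency, `log_target_freq`, and `freq_matched`.
#' @export
build_twoafc_trials <- function(lexA, lexB, n_trials = 64L, freq_cutoff = 1000L,
                                seed = 1L, log_tol = 0.25) {
  assert_lexicon(lexA, "lexA")
  assert_lexicon(lexB, "lexB")
  n_trials <- assert_count(n_trials, "n_trials", min = 1L)
  invA <- attr(lexA, "inventory") %||% unique(unlist(lexA$syllables))
  invB <- attr(lexB, "inventory") %||% unique(unlist(lexB$syllables))
  shared <- intersect(invA, invB)
  eligibleB <- vapply(lexB$syllables, function(s) all(s %in% shared), TRUE)

  with_substream(substream_seed(seed, "twoafc_trials"), {
    obligatory <- which(lexA$frequency > freq_cutoff)
    if (length(obligatory) > n_trials) {
      abort(sprintf("%d words exceed the frequency cutoff but only %d trials requested.",
                    length(obligatory), n_trials))
    }
    targets <- obligatory
    lf <- log(lexA$frequency)
    while (length(targets) < n_trials) {
      u <- runif(1, min(lf), max(lf))
      free <- setdiff(seq_len(nrow(lexA)), targets)
      cand <- free[which.min(abs(lf[free] - u))]
      targets <- c(targets, cand)
    }
    used_b <- integer(0)
    dist_idx <- vapply(targets, function(t) {
      cands <- which(eligibleB &
                       lexB$length == lexA$length[t] &
                       lexB$form != lexA$form[t])
      cands <- setdiff(cands, used_b)
      if (length(cands) == 0L) {
        abort(sprintf("No eligible distractor for target '%s' (length %d).",
                      lexA$form[t], lexA$length[t]))
      }
      d <- abs(log(lexB$frequency[cands]) - lf[t])
      best <- cands[d == min(d)]
      pick <- if (length(best) > 1L) sample(best, 1L) else best
      used_b <<- c(used_b, pick)
      pick
    }, 0L)
  })

  tibble::tibble(
    trial = seq_along(targets),
    target_rank = lexA$rank[targets],
    target_form = lexA$form[targets],
    target_freq = lexA$frequency[targets],
    target_length = lexA$length[targets],
    distractor_rank = lexB$rank[dist_idx],
    distractor_form = lexB$form[dist_idx],
    distractor_freq = lexB$frequency[dist_idx],
    distractor_length = lexB$length[dist_idx],
    log_target_freq = log(lexA$frequency[targets]),
    freq_matched = abs(log(lexB$frequency[dist_idx]) - log(lexA$frequency[targets])) <= log_tol
  )
}

#' Score 2AFC choices
#'
#' Joins choices to trials, marks correctness, and groups trials into
#' log-frequency ranges for plotting.
#'
#' @param trials Trial tibble from [build_twoafc_trials()].
#' @param choices Either a logical vector (`TRUE` = chose the target), or a
#'   data frame with columns `trial` and `chose_target` (as returned by
#'   [twoafc_responder()]).
#' @param n_ranges Number of equal-width log-frequency ranges.
#' @return The trial tibble with `chose_target`, `correct`, and `freq_range`.
#' @export
score_twoafc <- function(trials, choices, n_ranges = 4L) {
  stopifnot(is.data.frame(trials))
  if (is.data.frame(choices)) {
    if (!all(c("trial", "chose_target") %in% names(choices))) {
      abort("`choices` data frame needs columns `trial` and `chose_target`.")
    }
    keep <- intersect(names(choices), c("trial", "chose_target", "participant"))
    out <- dplyr::inner_join(trials, choices[, keep, drop = FALSE], by = "trial")
    if (nrow(out) != nrow(trials)) abort("Missing choices for some trials.")
  } else {
    if (length(choices) != nrow(trials) || anyNA(choices)) {
      abort("Need one non-missing choice per trial.")
    }
    out <- dplyr::mutate(trials, chose_target = as.logical(choices))
  }
  rng <- range(out$log_target_freq)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_ranges + 1L)
  dplyr::mutate(out,
                correct = .data$chose_target,
                freq_range = cut(.data$log_target_freq, breaks, include.lowest = TRUE))
}

half_logit_p <- function(beta, logf) 0.5 + 0.5 * plogis(beta[1] + beta[2] * logf)

half_logit_nll <- function(beta, logf, correct) {
  p <- half_logit_p(beta, logf)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(ifelse(correct, log(p), log(1 - p)))
}

#' Fit the half-logit psychometric model
#'
#' Maximum-likelihood fit of 2AFC accuracy as a function of log target
#' frequency with a chance floor:
#' `p(f) = 0.5 + 0.5 * logistic(beta0 + beta1 * ln f)`,
#' the standard psychometric form for a task where guessing yields 50%.
#' Optimized by BFGS from the fixed starting point (0, 0); Wald 95% CIs are
#' taken from the observed-information Hessian. Complete separation (a
#' coefficient running to the boundary) is reported with a warning flag
#' rather than an error.
#'
#' @param results Scored trial tibble from [score_twoafc()] (needs
#'   `correct` and `log_target_freq` — or `target_freq`).
#' @return An object of class `seglab_half_logit`: coefficients `beta0`,
#'   `beta1`, `vcov`, `loglik`, `ci` (2 x 2), `n`, `separation` flag,
#'   `converged` flag.
#' @export
fit_half_logit <- function(results) {
  stopifnot(is.data.frame(results), "correct" %in% names(results))
  logf <- results$log_target_freq %||% log(results$target_freq)
  correct <- as.logical(results$correct)
  if (length(unique(logf)) < 2L) abort("Need responses at >= 2 distinct frequencies.")
  opt <- optim(c(0, 0), half_logit_nll, logf = logf, correct = correct,
               method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par
  separation <- any(abs(beta) > 15)
  vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  ci <- cbind(beta - 1.96 * se, beta + 1.96 * se)
  dimnames(ci) <- list(c("beta0", "beta1"), c("low", "high"))
  if (separation) {
    warn("Half-logit fit reached a coefficient boundary (possible complete separation).")
  }
  structure(list(
    beta0 = beta[1], beta1 = beta[2], vcov = vc, se = se,
    loglik = -opt$value, ci = ci, n = length(correct),
    separation = separation, converged = opt$convergence == 0,
    data = tibble::tibble(log_target_freq = logf, correct = correct)
  ), class = "seglab_half_logit")
}

#' Predicted accuracy from a half-logit fit
#'
#' @param object A `seglab_half_logit` fit.
#' @param newdata Optional data frame with `log_target_freq` (or
#'   `target_freq`); defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted accuracies in `[0.5, 1]`.
#' @export
predict.seglab_half_logit <- function(object, newdata = NULL, ...) {
  logf <- if (is.null(newdata)) object$data$log_target_freq
          else newdata$log_target_freq %||% log(newdata$target_freq)
  half_logit_p(c(object$beta0, object$beta1), logf)
}

#' @export
print.seglab_half_logit <- function(x, ...) {
  cat(sprintf(
    "Half-logit psychometric fit (n = %d)\n  accuracy = 0.5 + 0.5 * logistic(%.3f + %.3f * ln f)\n  log-likelihood %.2f%s\n",
    x$n, x$beta0, x$beta1, x$loglik,
    if (x$separation) "  [separation flag]" else ""))
  invisible(x)
}

#' @export
#' @method tidy seglab_half_logit
tidy.seglab_half_logit <- function(x, ...) {
  tibble::tibble(
    term = c("beta0", "beta1"),
    estimate = c(x$beta0, x$beta1),
    std.error = x$se,
    statistic = c(x$beta0, x$beta1) / x$se,
    p.value = 2 * pnorm(-abs(c(x$beta0, x$beta1) / x$se)),
    conf.low = x$ci[, "low"],
    conf.high = x$ci[, "high"]
  )
}

#' @export
#' @method glance seglab_half_logit
glance.seglab_half_logit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n,
                 separation = x$separation, converged = x$converged)
}
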