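# Inference: the frequency x boundary regression on location decisions and
# Beta-posterior binomial intervals.

#' Regression of segmentation correctness on log frequency and boundary status
#'
#' Fits `correct ~ log(freq) * bound` to location decisions, where `bound`
#' indicates whether a true boundary is present at the gap. The pooled fit
#' adds participant fixed effects when more than one participant is present
#' (a small-sample approximation to a by-subject random-effects structure),
#' and independent per-participant fits are returned alongside. Significance
#' uses the z-approximation.
#'
#' @param decisions Output of [classify_locations()] (possibly row-bound
#'   over participants).
#' @param family `"logistic"` (binomial GLM, default for the binary
#'   outcome) or `"linear"` (linear probability model).
#' @return An object of class `seglab_freq_bound`: `pooled` (the fitted
#'   model), `per_participant` (named list of fits), `family`, `terms`.
#' @export
fit_freq_bound_model <- function(decisions, family = c("logistic", "linear")) {
  family <- match.arg(family)
  need <- c("correct", "log_freq", "is_boundary", "participant")
  stopifnot(is.data.frame(decisions), all(need %in% names(decisions)))
  if (length(unique(decisions$log_freq)) < 2L) {
    abort("Singular design: decisions carry a single frequency value.")
  }
  if (length(unique(decisions$is_boundary)) < 2L) {
    abort("Both boundary and word-internal gaps are required.")
  }
  d <- dplyr::mutate(decisions,
                     correct = as.numeric(.data$correct),
                     bound = as.numeric(.data$is_boundary))
  multi <- length(unique(d$participant)) > 1L
  form <- if (multi) correct ~ log_freq * bound + participant else correct ~ log_freq * bound
  fit1 <- function(dat, f) {
    if (family == "logistic") glm(f, data = dat, family = binomial())
    else lm(f, data = dat)
  }
  pooled <- fit1(d, form)
  per <- lapply(split(d, d$participant), fit1, f = correct ~ log_freq * bound)
  structure(list(pooled = pooled, per_participant = per, family = family,
                 terms = c("(Intercept)", "log_freq", "bound", "log_freq:bound")),
            class = "seglab_freq_bound")
}

coef_table <- function(fit, participant) {
  s <- summary(fit)$coefficients
  tibble::tibble(
    participant = participant,
    term = rownames(s),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 1] / s[, 2],
    p.value = 2 * pnorm(-abs(s[, 1] / s[, 2]))
  )
}

#' @export
#' @method tidy seglab_freq_bound
tidy.seglab_freq_bound <- function(x, ...) {
  dplyr::bind_rows(
    coef_table(x$pooled, "pooled"),
    dplyr::bind_rows(lapply(names(x$per_participant), function(p) {
      coef_table(x$per_participant[[p]], p)
    }))
  )
}

#' @export
#' @method glance seglab_freq_bound
glance.seglab_freq_bound <- function(x, ...) {
  tibble::tibble(family = x$family,
                 nobs = length(x$pooled$fitted.values),
                 n_participants = length(x$per_participant))
}

#' @export
print.seglab_freq_bound <- function(x, ...) {
  cat(sprintf("Frequency x boundary model (%s), pooled coefficients:\n", x$family))
  print(coef_table(x$pooled, "pooled"), n = Inf)
  invisible(x)
}

#' Beta-posterior binomial interval
#'
#' Equal-tailed 95% posterior interval for a binomial proportion under a
#' Beta prior: the posterior is `Beta(successes + a, trials - successes +
#' b)`. The default is the Jeffreys prior (1/2, 1/2); `prior = c(1, 1)`
#' gives the uniform prior. With zero trials the interval is the prior's
#' own quantiles and is flagged.
#'
#' @param successes,trials Integer vectors (recycled).
#' @param prior Length-2 numeric `(a, b)`.
#' @param level Posterior mass (default 0.95, equal-tailed).
#' @return A tibble: `successes`, `trials`, `estimate`, `low`, `high`,
#'   `flagged`.
#' @export
#' @examples
#' beta_binomial_interval(5, 10) # symmetric about 0.5
beta_binomial_interval <- function(successes, trials, prior = c(0.5, 0.5),
                                   level = 0.95) {
  stopifnot(length(prior) == 2L, all(prior > 0))
  n <- max(length(successes), length(trials))
  successes <- rep_len(successes, n)
  trials <- rep_len(trials, n)
  if (any(successes < 0 | successes > trials)) {
    abort("`successes` must lie in [0, trials].")
  }
  a <- successes + prior[1]
  b <- trials - successes + prior[2]
  alpha <- (1 - level) / 2
  tibble::tibble(
    successes = successes,
    trials = trials,
    estimate = ifelse(trials > 0, successes / trials, NA_real_),
    low = qbeta(alpha, a, b),
    high = qbeta(1 - alpha, a, b),
    flagged = trials == 0L
  )
}

#' Moving-average smoother over log frequency
#'
#' A plot aid: sliding-window mean of a response over an ordered predictor
#' (used in place of a loess smoother on the binned accuracy figure).
#'
#' @param x Predictor (e.g. log frequency).
#' @param y Response (e.g. correctness 0/1).
#' @param window Window width in `x` units.
#' @param n_points Number of evaluation points.
#' @return A tibble with `x` and smoothed `y`.
#' @export
moving_average <- function(x, y, window = 1, n_points = 50L) {
  stopifnot(length(x) == length(y), window > 0)
  grid <- seq(min(x), max(x), length.out = n_points)
  sm <- vapply(grid, function(g) {
    w <- abs(x - g) <= window / 2
    if (any(w)) mean(y[w]) else NA_real_
  }, 0)
  tibble::tibble(x = grid, y = sm)
}
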