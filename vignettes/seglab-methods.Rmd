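---
title: "Simulating large-scale statistical word segmentation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating large-scale statistical word segmentation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seglab)
library(dplyr)
```

## What this package simulates

Statistical word segmentation experiments test whether listeners can discover
word forms in continuous speech using only distributional regularities — no
pauses at word edges, no prosody, no semantics. Small laboratory versions of
this task use a handful of words heard for a few minutes. seglab simulates the
large-scale version: a unique artificial language per participant with a
naturalistic (Zipfian) frequency profile, tens of thousands of tokens of
exposure, an explicit segmentation test on novel sentences scored like a
computational segmenter, and a two-alternative forced-choice (2AFC) retention
test years later.

No human data ship with the package. Synthetic responders with *known*
generative parameters take the place of participants, which turns every
analysis stage into a testable measurement instrument: if the scoring,
permutation-null, and regression machinery cannot recover the parameters we
planted, the machinery is wrong.

## The language model

A language is defined by four nested stochastic processes, all driven by one
master seed with named substreams (`substream_seed()`), so any stage can be
regenerated in isolation.

**Syllable inventory.** 24 consonants and 14 vowels combine exhaustively into
336 CV syllables (`build_syllable_inventory()`). Syllables are the atomic
units: words are syllable sequences and segmentation decisions happen at
syllable gaps.

**Zipfian lexicon.** 1000 word types share 60,000 tokens. Per-rank counts are
$f_r = \max(\mathrm{round}(C/r),\ \mathrm{floor})$ with the scale constant
$C$ solved numerically so the counts sum exactly to the token total
(`allocate_zipf_counts()`). The floor (default 10) is treated as a hard
minimum: a pure $C/r$ law over 1000 ranks would push the tail to about 8
tokens per type, so the floor is what makes the minimum count of 10 hold as a
realized property. The solve puts the rank-1 count at 7987 tokens. Rounding
residue is absorbed by rank 1, where it is relatively smallest.

**Word forms.** Lengths are shifted-Poisson, $\mathrm{Pois}(2) + 1$ (mean 3
syllables), drawn independently of rank — frequent words are not biased to be
short. Forms are uniform random syllable strings, resampled on collision
until all 1000 are distinct.

**Corpus.** The default *exact-count* mode lays out the full token multiset
(so realized frequencies equal the allocation exactly, and the printed
max/min counts are properties of every generated corpus, not expectations)
and arranges it with no word immediately repeating, enforced across the whole
stream including sentence boundaries. Arrangement is a random shuffle with
swap repair; for tight multisets near forced alternation the engine falls
back to a constrained greedy placement that takes a type as soon as its
remaining count reaches half the remaining slots. An i.i.d. multinomial mode
(`exact_counts = FALSE`) is available because either reading of "concatenated
according to the frequency distribution" is defensible; the exact-count mode
is the default because it makes the printed extreme counts exact. The stream
is then cut into sentences with shifted-Poisson lengths,
$\mathrm{Pois}(2) + 2$ words (mean 4 words, hence 12 syllables); the final
sentence is trimmed to make the token total exact, or merged into its
predecessor if trimming would leave a one-word sentence.

Test blocks (`generate_test_block()`) are sampled by the same sentence
process and kept only if their word sequence never occurred in training; 100
novel sentences average about 400 word tokens.

One deliberate non-goal: at 250 ms per syllable the 60,000-token corpus runs
to roughly 12.5 hours of nominal audio. We reproduce the token arithmetic,
not any particular wall-clock figure.

## Export formats

`corpus_to_gloss()` emits the orthographic test format — one sentence per
line, syllables space-separated, no boundary marks — and `read_gloss()`
inverts it losslessly given the gold gap file. `corpus_to_pho()` writes
MBROLA-style timing tracks: each syllable is split into consonant and vowel
at 125 ms each (the 250 ms syllable total is the design constant; the
internal 125/125 split is our choice), pitch anchored at a constant 100 Hz, a 200 ms silence line after
every sentence, and batches chunked to about five minutes without splitting a
sentence. Audio synthesis itself is out of scope.

## Synthetic participants

The package deliberately separates *measurement* from *mechanism*:

- `oracle_noisy_segmenter()` is the canonical harness: it marks true
  boundaries with probability `hit_rate` and word-internal gaps with
  probability `false_alarm_rate`, independently. It has no linguistic
  content, which is the point — its empirical hit/false-alarm rates must
  converge to the parameters, and any frequency dependence the analysis
  stack reports for it is a bug.
- `tp_segmenter()` is an illustrative mechanism: transitional probabilities
  $P(s_2 \mid s_1)$ estimated within sentences from the training corpus, a
  boundary wherever the TP falls below a threshold. Unseen bigrams count as
  TP 0, the conservative reading under which a novel juncture signals a
  boundary. The default threshold of 0.05 was chosen from the structure of
  the default language: across-boundary TPs concentrate below roughly 0.09
  and within-word TPs above roughly 0.03, and 0.05 sits in the crossover
  region. It is a learner parameter, not a fact about the task.
- `yoked_control_segmenter()` estimates TPs from the test block alone — a
  model of a participant who saw the test but never the training material.
- `chunk_segmenter()` is a frequency-chunk alternative: the most frequent
  attested n-grams form a chunk inventory that greedily parses each test
  sentence leftmost-longest.
- `periodic_segmenter()` reproduces the degenerate every-*k*-syllables
  strategy, and `detect_degenerate_strategy()` flags any exact fixed-period
  lattice (including the all-empty response, period infinity). The detector
  covers any constant period, not just the classic every-other-syllable
  pattern: the interpretability failure is identical.
- `twoafc_responder()` inverts the half-logit psychometric model (below), so
  its coefficients are recoverable by the fitting stage.

Which mechanism best mimics human asymmetries (e.g. precision exceeding
recall) is left open deliberately; the learners are instruments for testing
the pipeline, not cognitive claims.

## Scoring and the permutation null

Responses are scored by strict gap matching — no near-miss credit. A hit is a
marked gap at a true boundary; precision is hits/(hits + false alarms),
recall hits/(hits + misses), F their harmonic mean. Counts are pooled over
the whole test (micro-average) before the ratios are taken, because the
chance baseline is defined on whole-test F; 0/0 ratios are defined as 0.

The chance baseline shuffles each sentence's own marks: `n_reps` simulated
segmentations per sentence, each placing that sentence's $m$ marks uniformly
among its $G$ gaps, keeping $m$ fixed. Because micro-averaged F equals
$2H/(M+K)$ — $H$ total hits, $M$ total marks, $K$ total boundaries — a
replicate's F is determined by its per-sentence hit counts, which under
uniform placement are exactly hypergeometric ($k$ boundary gaps among $G$,
$m$ drawn). The engine therefore draws `rhyper()` variates rather than
materializing gap sets; `permute_gaps()` exposes the explicit shuffle, and
the tests verify the equivalence against exhaustive enumeration for small
sentences (the expected per-sentence hit count is $mk/G$). The one-sided
p-value uses the add-one correction $(b+1)/(n+1)$, counting the observed
response among the samples.

## Location-level frequency analysis

`classify_locations()` turns every gap into a decision record: boundary gaps
are labelled with the higher of the two adjacent words' frequencies,
word-internal gaps with their containing word's frequency, and a decision is
correct when marked-if-and-only-if-boundary. With mean word length 3,
word-internal gaps outnumber boundary gaps. `bin_by_log_frequency()` bins
decisions on log frequency with equal-tailed 95% Beta-posterior intervals
per cell, and `fit_freq_bound_model()` fits
`correct ~ log(freq) * bound`, logistic by default for the binary outcome
(a linear-probability option exists because either link is defensible for
this design; neither is asserted as canonical). With several participants
the pooled fit uses participant fixed effects, with independent
per-participant fits alongside: a maximal crossed random-effects structure is
not estimable from a handful of subjects, and on simulated data the true
structure is known anyway, so the fixed-effects approximation is the honest
choice. Significance uses the z-approximation throughout.

The binned-accuracy figure uses a windowed moving average as its smoother —
a deliberate simplification of loess, adequate for a plot aid.

## The 2AFC retention test

`build_twoafc_trials()` builds 64 trials. Every word with training frequency
above 1000 is an obligatory target — under the default allocation exactly 7
words qualify — and the remaining slots sample targets uniformly on the
log-frequency range, each draw mapped to the nearest unused word. Distractors
come from *another* participant's lexicon, matched on syllable length,
composed only of syllables present in both inventories, never form-identical
to the target, and chosen as the closest log-frequency match (a |Δlog f| ≤
0.25 match is flagged as such; the closest candidate is used regardless,
failing hard only when no length/syllable-eligible candidate exists). Ties
break by seeded random draw; distractors are not reused. Stratification of the sampled
targets and the tie-breaking rule are genuinely open choices; both are
recorded here as ours.

Accuracy is modelled with a chance-floored ("half-logit") psychometric
function,
$$p(f) = \tfrac12 + \tfrac12\,\sigma(\beta_0 + \beta_1 \ln f),$$
the standard 2AFC form: guessing yields 50%, so the logistic is compressed
into [0.5, 1]. `fit_half_logit()` maximizes the Bernoulli likelihood with
BFGS from the fixed start (0, 0) and reports Wald 95% CIs from the
observed-information Hessian; a coefficient beyond ±15 on the linear
predictor flags separation (e.g. all-correct data) instead of erroring. The
fitted curve can never dip below 0.5, and the fit's likelihood is never worse
than the chance model's — both are asserted in the test suite.

`beta_binomial_interval()` implements the binomial intervals: equal-tailed
quantiles of the Beta(successes + a, failures + b) posterior, Jeffreys
(a = b = 1/2) by default — the conventional reading of a "non-informative"
Beta prior — with the uniform prior one argument away.

## The end-to-end experiment

`run_experiment()` composes everything under `experiment_config()`, whose
defaults are the study conditions: 4 participants, 1000 types / 60,000
tokens, floor 10, mean word length 3, mean sentence length 4, two interim
tests of 100 novel sentences (the second on fresh material with no further
exposure), one yoked control per participant, 10,000 permutation replicates,
and a 64-trial 2AFC with cutoff 1000 whose distractors come from the next
participant's language. Every stochastic stage draws a named substream of
the master seed, so two runs of one config are identical and any artifact is
reproducible in isolation. At these defaults the full pipeline completes in
well under a minute on one CPU.

The test suite runs the pipeline at reduced sizes (e.g. 120-type, 3600-token
languages, 400 permutation replicates) purely to keep the suite snappy; the
acceptance checks regenerate the full-scale configuration.

## What the simulations do and do not show

The synthetic learners make the pipeline falsifiable, and the qualitative
ordering the defaults produce — trained learners above yoked controls above
the permutation ceiling — is the pattern this experimental design is built
to detect. But
the human performance *levels* depend on human memory and cannot be
reproduced from a response model with invented parameters; nothing here
should be read as a quantitative claim about human segmentation accuracy.
Similarly, the generator emulates the language's statistics (Zipfian
frequencies, length distributions, adjacency constraint), not speech: there
is no coarticulation, no prosodic variation, no acoustic confusability, so a
learner's difficulty here is a lower bound on the real task's difficulty in
those respects.

Known numerical edges: the Zipf solve bisects a monotone step function, so
the returned $C$ is the smallest value reaching the token total and results
are platform-stable; lexicon collision resampling can in principle exhaust
its budget if the syllable inventory is tiny relative to the type count (it
errors, naming the length stratum); and the half-logit Hessian is singular
under separation, in which case the CIs are reported as NA alongside the
separation flag.
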