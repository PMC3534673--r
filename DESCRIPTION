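Package: seglab
Title: Simulated Large-Scale Artificial-Language Segmentation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates large Zipfian artificial languages (1000 word types,
    60,000 tokens, shifted-Poisson word and sentence lengths, a 336 CV
    syllable inventory), exports orthographic glosses and synthesis timing
    files, simulates learner segmentation and two-alternative forced-choice
    responses, scores segmentations with precision/recall/F against gold
    boundaries, builds within-sentence permutation-null chance baselines,
    runs location-level frequency analyses with Beta-posterior binomial
    intervals, and fits half-logit psychometric accuracy-frequency models.
    All stages operate on tidy data frames and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
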