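Package: mmnpipe
Title: Mismatch Negativity Analysis for Auditory Oddball EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for deriving and testing the auditory
    mismatch negativity (MMN) from multichannel oddball EEG. Provides a
    synthetic-data module that emulates simple (frequency) and pattern
    (three-tone pitch regularity) oddball studies with configurable
    fronto-central MMN structure and colored noise; preprocessing
    (zero-phase band-pass filtering, linked-mastoid re-referencing,
    epoching, baseline correction, amplitude-threshold artifact rejection);
    deviant-minus-standard difference waves with per-subject peak-latency
    and mean-amplitude measures; global field power normalization and the
    topographic dissimilarity (DISS) randomization test; and 2x2
    mixed-design ANOVA with partial eta squared plus paired, independent,
    and summary-statistics t tests with Cohen's d. Results are tibbles with
    broom-style tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
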