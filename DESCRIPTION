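Package: palaterry
Title: Multiverse Bradley-Terry Analysis of Paired Feed-Preference Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for estimating feed palatability from paired-intake
    preference trials. Intake pairs are coded as win, loss or tie at a
    grid of preference thresholds (a limited multiverse analysis), each
    branch is fitted with a Bradley-Terry model in which one feed is the
    zero reference, and inference uses quasi-variances: per-item quasi
    standard errors, pooled-SE pairwise z-tests, confidence intervals
    and compact letter displays. Includes a Monte-Carlo power engine for
    paired-preference designs and a synthetic-trial generator that
    emulates short-term cattle feed-bunk experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
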