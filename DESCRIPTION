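Package: tdsim
Title: Similarity Indices and Outlier Screening for Temporal Dominance of
    Sensations Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual-trial analysis of temporal dominance of
    sensations (TDS) data. Trials are modelled as piecewise-constant binary
    dominance functions on normalized time, discretized exactly into R equal
    intervals, and compared with a normalized similarity index whose dynamic
    level R tunes the weight given to the timing of attribute selection.
    Includes per-trial similarity to the panel centroid, cross-R correlation
    grids with R-recommendation heuristics, a normality-gated one-sided
    outlier screen (mean minus 1.64 or 2.33 standard deviations, with an
    interquartile-range fallback and a univariate robust option), and a
    semi-Markov synthetic trial generator with a strawberry-like preset and
    outlier-archetype injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
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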