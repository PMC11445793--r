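Package: dreamsent
Title: Word-for-Word Emotion Dynamics in Dream Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Objectively classifies and quantifies sequential (word-for-word)
    emotion within dream reports. Assigns each word a continuous valence
    rating from a sentiment lexicon, applies a sliding-window
    standardization to produce a "dream chart", demarcates its peaks and
    troughs, and derives six per-dream emotion indicators: total peaks,
    total troughs, positive / negative / overall emotion intensity
    (trapezoid-rule area under the curve of the peaks and troughs), and the
    emotion gradient of a polynomial trendline. Indicators can be
    correlated against external sleep, state, and trait variables with a
    tie-aware rank-correlation protocol. Includes a synthetic dream-report
    generator with planted ground-truth structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
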