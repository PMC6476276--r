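Package: sentistream
Title: Active-Learning Sentiment Surveillance for Social-Media Health Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for tracking health-related sentiment in
    streams of short social-media posts. Posts are filtered by keyword,
    scored by a bag-of-words classifier, and prioritized for human labeling
    by a blend of label uncertainty and recency. Labels are collected through
    branching question sequences from multiple annotators, aggregated by
    strict-majority consensus, and fed back into the classifier in an active
    learning loop. Trend analytics compute per-class binned counts, moving
    averages, a rolling positive-among-polar ratio, a normalized sentiment
    index (r - mu)/sigma, and a lowess-smoothed trend curve. A synthetic
    stream generator with injectable distribution shifts and simulated
    annotators makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    glmnet,
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
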