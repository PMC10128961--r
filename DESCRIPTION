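Package: wsnr
Title: Weighted Signal-to-Noise Ratio Feature Selection for Two-Class
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filter-style gene selection for two-class high-dimensional
    expression matrices. Ranks features by the product of their absolute
    linear support-vector-machine hyperplane coefficient and their
    signal-to-noise ratio (W_SNR), alongside baseline scorers (plain SNR,
    Welch t / sigF weight-times-p-value, Wilcoxon rank-sum). Includes a
    synthetic-data generator with planted informative features, optional
    outlier contamination and injected noise variables, and a repeated
    train/test-split benchmarking harness with random-forest and
    k-nearest-neighbour downstream classifiers, error-rate aggregation and
    win-loss summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
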