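# wsnr

Filter-style gene selection for two-class, high-dimensional expression
data, built around the **weighted signal-to-noise ratio**. For gene *j*
with per-class means *m₀ⱼ, m₁ⱼ* and standard deviations *s₀ⱼ, s₁ⱼ*:

```
SNR_j     = |m0_j - m1_j| / (s0_j + s1_j)
(W_SNR)_j = |w_j| * SNR_j
```

where *wⱼ* is the *j*-th coefficient of a linear soft-margin SVM fit on
standardized features. Genes are ranked by `(W_SNR)_j` in descending
order and the top *K* feed the downstream classifier. The package also
implements the usual baselines — plain SNR, Welch *t*, sigF
(`|w_j| × p_j`, smaller is better) and the Wilcoxon rank-sum p-value —
plus:

* a synthetic-data generator with planted informative features, optional
  outlier contamination and injected noise variables (scenarios S1/S2),
* a repeated 70/30-split benchmarking harness (random forest and kNN
  downstream, paired splits across methods, win–loss summaries),
* tidyverse-style interfaces: data frames in, tibbles out, `tidy()`,
  `glance()` and `autoplot()` methods, and a small CLI.

Intended users: anyone comparing univariate/SVM-hybrid gene filters on
two-class expression matrices, or needing a controlled simulation bed
for such comparisons.

## Worked example

```r
library(wsnr)

# A contaminated simulated dataset: 100 samples x 120 genes, 5 planted
# informative genes, 20 pure-noise genes.
sim <- simulate_expression("S1", seed = 42)
sim
#> # Simulated two-class expression data (scenario S1)
#> #  100 samples x 120 features, 5 planted informative, balance 0.57
#> #  planted: gene049, gene047, gene005, gene090, gene009

# Rank genes by W_SNR and keep the top 5.
select_top_k(wsnr_scores(sim$data), 5)
#> # Top-5 selection by WSNR
#> # A tibble: 120 x 5
#>    rank index feature  score selected
#> 1     1     9 gene009 0.166  TRUE
#> 2     2     5 gene005 0.160  TRUE
#> 3     3    90 gene090 0.125  TRUE
#> 4     4    49 gene049 0.0688 TRUE
#> 5     5    38 gene038 0.0684 TRUE
```

Four of the five selected genes are planted ground truth. The
repeated-split harness estimates downstream error rates; here a small
run comparing W_SNR with the rank-sum baseline:

```r
res <- run_simulation_study("S1", methods = c("wsnr", "wilcoxon"),
                            k_values = 5, classifiers = "rf",
                            n_datasets = 2, n_repeats = 10, seed = 1)
tidy(res)
#> # A tibble: 2 x 7
#>   dataset method   classifier     k mean_error n_repeats n_failed
#> 1 S1      wilcoxon rf             5      0.305        20        0
#> 2 S1      wsnr     rf             5      0.255        20        0
win_loss(res)
#> ...
#> # Total wins per method:
#>   method  wins
#> 1 wsnr       1
```

`mean_error` is the mean test misclassification rate over the repeated
70/30 splits: with 5 selected genes and a 500-tree random forest, W_SNR
errs on 25.5% of held-out samples versus 30.5% for the Wilcoxon filter,
and takes the win for this (dataset, classifier) pair.

Real data enter through `read_expression()` (delimited text, label
column, samples-in-rows or genes-in-rows), and `autoplot()` draws the
standard error-rate bar charts. A thin command-line wrapper lives at
`inst/cli/wsnr.R` with `select`, `simulate` and `benchmark`
subcommands; every run writes a JSON manifest so it can be reproduced.

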