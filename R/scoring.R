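#' Per-feature discriminative scores
#'
#' All scorers take a samples-by-features data frame with a two-valued label
#' column and return a tibble with one row per feature, carrying the method
#' name and its ranking direction as attributes. Scores chain directly into
#' [select_top_k()].
#'
#' * `snr_scores()` — signal-to-noise ratio: |mean0 - mean1| / (sd0 + sd1),
#'   class standard deviations with the n-1 denominator. Higher is better.
#' * `svm_weights()` — absolute primal coefficients |w_j| of a linear
#'   soft-margin SVM fit on per-feature standardized values. Higher is better.
#' * `wsnr_scores()` — the W_SNR score, the elementwise product
#'   |w_j| * SNR_j. Higher is better.
#' * `t_statistics()` — per-feature Welch t statistic with two-sided p-value
#'   under Welch-Satterthwaite degrees of freedom; ranked by |t|.
#' * `sigf_scores()` — the sigF score |w_j| * p_j with p_j the two-sided
#'   Welch p-value. Lower is better.
#' * `wilcoxon_scores()` — two-sided Mann-Whitney rank-sum p-value (exact
#'   when the two groups total at most 25 samples and are tie-free, normal
#'   approximation with tie and continuity correction otherwise). Lower is
#'   better.
#'
#' @param data Data frame of samples by features with a label column.
#' @param label Name of the label column. Default `"class"`.
#' @param cost Soft-margin cost parameter C of the linear SVM. Default 1.
#' @return A tibble of class `wsnr_scores` with columns `feature` and
#'   `score` (plus method-specific columns), and attributes `method` and
#'   `direction` (`"higher"` or `"lower"`).
#' @name feature-scores
#' @examples
#' d <- data.frame(class = rep(0:1, each = 5),
#'                 g1 = c(rnorm(5), rnorm(5, 3)), g2 = rnorm(10))
#' snr_scores(d)
#' wsnr_scores(d) |> select_top_k(1)
NULL

new_feature_scores <- function(tbl, method, direction) {
  structure(tbl,
            class = c("wsnr_scores", class(tibble::tibble())),
            method = method, direction = direction)
}

#' @export
print.wsnr_scores <- function(x, ...) {
  cat("# Feature scores:", attr(x, "method"),
      sprintf("(%s is better)\n", attr(x, "direction")))
  NextMethod()
}

class_stats <- function(X, y) {
  X0 <- X[y == 0, , drop = FALSE]
  X1 <- X[y == 1, , drop = FALSE]
  list(m0 = colMeans(X0), m1 = colMeans(X1),
       v0 = apply(X0, 2, stats::var), v1 = apply(X1, 2, stats::var),
       n0 = nrow(X0), n1 = nrow(X1))
}

#' @rdname feature-scores
#' @export
snr_scores <- function(data, label = "class") {
  data <- as_expression_data(data, label)
  xy <- split_xy(data, label)
  st <- class_stats(xy$X, xy$y)
  denom <- sqrt(st$v0) + sqrt(st$v1)
  score <- abs(st$m0 - st$m1) / denom
  # Eq-7 is undefined when both class sds are zero: equal means score 0;
  # unequal means (a perfectly separating constant feature) take the largest
  # finite score in the vector.
  degenerate <- denom == 0
  if (any(degenerate)) {
    sep <- degenerate & abs(st$m0 - st$m1) > 0
    score[degenerate] <- 0
    if (any(sep)) {
      top <- if (any(!degenerate)) max(score[!degenerate]) else 1
      score[sep] <- top
      rlang::inform(
        paste0(sum(sep), " constant-but-separating feature(s) assigned the ",
               "largest finite SNR in the vector."),
        class = "wsnr_snr_degenerate")
    }
  }
  new_feature_scores(
    tibble::tibble(feature = xy$feature_names, score = unname(score)),
    method = "SNR", direction = "higher")
}

#' @rdname feature-scores
#' @export
svm_weights <- function(data, label = "class", cost = 1) {
  stopifnot(is.numeric(cost), cost > 0)
  data <- as_expression_data(data, label)
  xy <- split_xy(data, label)
  if (any(!is.finite(xy$X))) {
    rlang::abort("Expression values must be finite for the SVM fit.",
      class = "wsnr_validation_error")
  }
  Xs <- standardize_columns(xy$X)
  fit <- tryCatch(
    e1071::svm(x = Xs, y = factor(xy$y, levels = c(0, 1)),
               kernel = "linear", cost = cost, scale = FALSE),
    error = function(e) {
      rlang::abort(paste0("Linear SVM fit failed: ", conditionMessage(e)),
        class = "wsnr_svm_error", parent = e)
    })
  w <- drop(crossprod(fit$coefs, fit$SV))
  if (any(!is.finite(w))) {
    rlang::abort("Linear SVM fit did not converge to finite coefficients.",
      class = "wsnr_svm_error")
  }
  new_feature_scores(
    tibble::tibble(feature = xy$feature_names, score = abs(unname(w))),
    method = "SVMW", direction = "higher")
}

# Per-column standardization; constant columns become all-zero (they can
# carry no hyperplane weight).
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

#' @rdname feature-scores
#' @export
wsnr_scores <- function(data, label = "class", cost = 1) {
  data <- as_expression_data(data, label)
  w <- svm_weights(data, label, cost = cost)
  snr <- snr_scores(data, label)
  new_feature_scores(
    tibble::tibble(feature = w$feature, score = w$score * snr$score,
                   weight = w$score, snr = snr$score),
    method = "WSNR", direction = "higher")
}

#' @rdname feature-scores
#' @export
t_statistics <- function(data, label = "class") {
  data <- as_expression_data(data, label)
  xy <- split_xy(data, label)
  st <- class_stats(xy$X, xy$y)
  se2 <- st$v0 / st$n0 + st$v1 / st$n1
  stat <- (st$m0 - st$m1) / sqrt(se2)
  df <- se2^2 / ((st$v0 / st$n0)^2 / (st$n0 - 1) + (st$v1 / st$n1)^2 / (st$n1 - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  zero_se <- se2 == 0
  if (any(zero_se)) {
    diffm <- (st$m0 - st$m1)[zero_se]
    stat[zero_se] <- ifelse(diffm == 0, 0, sign(diffm) * Inf)
    p[zero_se] <- ifelse(diffm == 0, 1, 0)
    df[zero_se] <- NA_real_
  }
  new_feature_scores(
    tibble::tibble(feature = xy$feature_names,
                   score = abs(unname(stat)), statistic = unname(stat),
                   p_value = unname(p), df = unname(df)),
    method = "TSTAT", direction = "higher")
}

#' @rdname feature-scores
#' @export
sigf_scores <- function(data, label = "class", cost = 1) {
  data <- as_expression_data(data, label)
  w <- svm_weights(data, label, cost = cost)
  tt <- t_statistics(data, label)
  new_feature_scores(
    tibble::tibble(feature = w$feature, score = w$score * tt$p_value,
                   weight = w$score, p_value = tt$p_value),
    method = "SIGF", direction = "lower")
}

#' @rdname feature-scores
#' @export
wilcoxon_scores <- function(data, label = "class") {
  data <- as_expression_data(data, label)
  xy <- split_xy(data, label)
  x0 <- xy$X[xy$y == 0, , drop = FALSE]
  x1 <- xy$X[xy$y == 1, , drop = FALSE]
  p <- vapply(seq_len(ncol(xy$X)), function(j) {
    ranksum_p(x0[, j], x1[, j])
  }, numeric(1))
  new_feature_scores(
    tibble::tibble(feature = xy$feature_names, score = p),
    method = "WILC", direction = "lower")
}

# Two-sided rank-sum p-value; exact for tie-free groups totalling <= 25,
# normal approximation with tie and continuity correction otherwise.
ranksum_p <- function(a, b) {
  vals <- c(a, b)
  if (all(vals == vals[1])) return(1)
  n <- length(vals)
  exact <- n <= 25 && anyDuplicated(vals) == 0
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Score features by a named method
#'
#' Dispatcher over the individual scorers, used by the evaluation harness.
#'
#' @inheritParams feature-scores
#' @param method One of `"wsnr"`, `"snr"`, `"svmw"`, `"tstat"`, `"sigf"`,
#'   `"wilcoxon"` (case-insensitive; `"wilc"` is accepted).
#' @return A `wsnr_scores` tibble.
#' @export
score_features <- function(data, method, label = "class", cost = 1) {
  method <- tolower(method)
  if (method == "wilc") method <- "wilcoxon"
  switch(method,
    wsnr = wsnr_scores(data, label, cost = cost),
    snr = snr_scores(data, label),
    svmw = svm_weights(data, label, cost = cost),
    tstat = t_statistics(data, label),
    sigf = sigf_scores(data, label, cost = cost),
    wilcoxon = wilcoxon_scores(data, label),
    rlang::abort(paste0("Unknown scoring method: '", method, "'"),
      class = "wsnr_input_error"))
}
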