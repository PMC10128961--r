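# Small dataset builders used across the suite.

# Two-class data frame from explicit per-class feature values.
toy_data <- function(..., y = NULL) {
  feats <- list(...)
  n <- length(feats[[1]])
  if (is.null(y)) y <- rep(c(0L, 1L), each = n / 2)
  tibble::as_tibble(c(list(class = y), feats))
}

# Random tie-free tiny dataset (continuous values, so the exact rank-sum
# regime applies almost surely).
random_tiny <- function(seed, n0 = NULL, n1 = NULL, d = NULL) {
  set.seed(seed)
  n0 <- n0 %||% sample(2:6, 1)
  n1 <- n1 %||% sample(2:6, 1)
  d <- d %||% sample(1:5, 1)
  X <- matrix(stats::rnorm((n0 + n1) * d), ncol = d)
  colnames(X) <- paste0("g", seq_len(d))
  dplyr::bind_cols(tibble::tibble(class = rep(c(0L, 1L), c(n0, n1))),
                   tibble::as_tibble(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
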