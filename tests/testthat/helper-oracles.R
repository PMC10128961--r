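# Independent brute-force oracles. These deliberately use naive loops and
# first-principles formulas so they share no code path with the package.

oracle_snr <- function(x0, x1) {
  m0 <- sum(x0) / length(x0)
  m1 <- sum(x1) / length(x1)
  s0 <- sqrt(sum((x0 - m0)^2) / (length(x0) - 1))
  s1 <- sqrt(sum((x1 - m1)^2) / (length(x1) - 1))
  abs(m0 - m1) / (s0 + s1)
}

oracle_welch <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  v0 <- sum((x0 - mean(x0))^2) / (n0 - 1)
  v1 <- sum((x1 - mean(x1))^2) / (n1 - 1)
  se2 <- v0 / n0 + v1 / n1
  t <- (mean(x0) - mean(x1)) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n, n0)
# group assignments of the observed values.
oracle_wilcoxon_enum <- function(x0, x1) {
  n0 <- length(x0)
  vals <- c(x0, x1)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2
  combos <- utils::combn(length(vals), n0)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n0 * (n0 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Hard-margin maximum-margin separator weights for 1-D or 2-D separable
# data by direction search: for a unit direction u, the geometric margin is
# half the projection gap between the classes; |w| = |u| / margin at the
# best direction. Grid search plus golden-section refinement.
oracle_margin_weights <- function(X, y) {
  X <- as.matrix(X)
  gap <- function(u) {
    proj <- X %*% u
    (min(proj[y == 1]) - max(proj[y == 0])) / 2
  }
  if (ncol(X) == 1) {
    g_pos <- gap(matrix(1))
    g <- max(g_pos, gap(matrix(-1)))
    stopifnot(g > 0)
    return(abs(1 / g))
  }
  stopifnot(ncol(X) == 2)
  obj <- function(th) gap(c(cos(th), sin(th)))
  grid <- seq(0, 2 * pi, length.out = 20001)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  opt <- stats::optimize(obj, lower = grid[max(1, i - 2)],
                         upper = grid[min(length(grid), i + 2)],
                         maximum = TRUE, tol = 1e-12)
  stopifnot(opt$objective > 0)
  abs(c(cos(opt$maximum), sin(opt$maximum)) / opt$objective)
}

# Column standardization matching the package's convention (for feeding
# the margin oracle the same values the SVM sees).
standardize_for_oracle <- function(X) {
  apply(as.matrix(X), 2, function(v) (v - mean(v)) / stats::sd(v))
}
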