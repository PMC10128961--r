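#' Simulate two-class expression data with planted informative features
#'
#' Generates an n-by-d matrix whose first `round(normal_fraction * d_base)`
#' base columns are iid standard normal and the rest iid standard uniform.
#' A coefficient vector beta is drawn from Uniform(`beta_range`), the linear
#' predictor is `eta = X beta + eps` with standard-normal noise, and binary
#' labels are Bernoulli with `p = plogis(b * eta + a)`. The `k_informative`
#' features with the largest |beta| are the planted ground truth.
#'
#' Scenario `"S1"` additionally contaminates each planted feature by
#' replacing a `contamination` fraction of its entries (rows chosen at
#' random per feature) with Normal(`outlier_mean`, `outlier_sd`) draws, and
#' appends `n_noise` pure-noise features drawn Normal(`noise_mean`,
#' `noise_sd`), for a total of `d_base + n_noise` columns. Scenario `"S2"`
#' is the clean control: no contamination, no appended noise columns.
#'
#' Labels are resampled (up to 100 attempts, same probabilities) if a draw
#' yields a single class. With a fixed `seed` the output is bit-reproducible;
#' draws happen in a fixed order (base columns, beta, eps, labels,
#' contamination rows then values per planted feature, noise columns).
#'
#' @param scenario `"S1"` (contaminated, default) or `"S2"` (clean).
#' @param n Number of samples. Default 100.
#' @param d_base Number of base features. Default 100.
#' @param n_noise Noise features appended in S1. Default 20.
#' @param k_informative Number of planted features. Default 5.
#' @param a,b Intercept and slope of the logistic link. Default 1.5 each.
#' @param beta_range Range of the uniform coefficient distribution.
#'   Default `c(-5, 5)`.
#' @param outlier_mean,outlier_spread Outlier distribution parameters (S1).
#'   Defaults 20 and 60.
#' @param noise_mean,noise_spread Noise-feature distribution parameters (S1).
#'   Defaults 5 and 10.
#' @param spread How the `*_spread` parameters are read: `"variance"`
#'   (default, the N(mean, sigma^2) textbook convention, so the outlier sd
#'   is `sqrt(60)`) or `"sd"`.
#' @param contamination Fraction of samples contaminated per planted
#'   feature in S1. Default 0.1.
#' @param normal_fraction Fraction of base columns drawn standard normal
#'   (the rest standard uniform). Default 0.5.
#' @param seed Optional integer seed.
#' @return A list of class `wsnr_simulation`: `data` (tibble with
#'   `sample_id`, `class`, feature columns), `informative_indices`,
#'   `informative` (names), `beta`, `scenario`, `contaminated` (named list
#'   of contaminated row indices per planted feature), and `config`.
#' @export
#' @examples
#' sim <- simulate_expression("S2", n = 40, d_base = 20, seed = 1)
#' glance(sim)
simulate_expression <- function(scenario = c("S1", "S2"), n = 100, d_base = 100,
                                n_noise = 20, k_informative = 5,
                                a = 1.5, b = 1.5, beta_range = c(-5, 5),
                                outlier_mean = 20, outlier_spread = 60,
                                noise_mean = 5, noise_spread = 10,
                                spread = c("variance", "sd"),
                                contamination = 0.2, normal_fraction = 0.5,
                                seed = NULL) {
  scenario <- match.arg(scenario)
  spread <- match.arg(spread)
  outlier_sd <- if (spread == "variance") sqrt(outlier_spread) else outlier_spread
  noise_sd <- if (spread == "variance") sqrt(noise_spread) else noise_spread
  stopifnot(n >= 4, d_base >= 1, k_informative >= 1, k_informative <= d_base,
            n_noise >= 0, length(beta_range) == 2, beta_range[1] < beta_range[2])
  if (scenario == "S1" && (contamination <= 0 || contamination > 1)) {
    rlang::abort("`contamination` must be in (0, 1] for scenario S1.",
      class = "wsnr_input_error")
  }
  if (!is.null(seed)) set.seed(seed)

  n_norm <- round(normal_fraction * d_base)
  X <- cbind(
    matrix(stats::rnorm(n * n_norm), nrow = n),
    matrix(stats::runif(n * (d_base - n_norm)), nrow = n))
  beta <- stats::runif(d_base, beta_range[1], beta_range[2])
  eps <- stats::rnorm(n)
  informative <- order(-abs(beta), seq_len(d_base))[seq_len(k_informative)]

  # S1 contamination happens before the label draw: the outlying values of
  # the planted features feed through the linear predictor, so the
  # contaminated scenario carries amplified (not destroyed) signal in those
  # features, which is what makes it the regime the method targets.
  contaminated <- list()
  if (scenario == "S1") {
    m <- round(contamination * n)
    for (j in informative) {
      rows <- sample.int(n, m)
      X[rows, j] <- stats::rnorm(m, outlier_mean, outlier_sd)
      contaminated[[length(contaminated) + 1L]] <- sort(rows)
    }
  }
  eta <- drop(X %*% beta) + eps
  p <- stats::plogis(b * eta + a)
  y <- draw_labels(p)
  # Appended noise features never enter the linear predictor.
  if (scenario == "S1" && n_noise > 0) {
    X <- cbind(X, matrix(stats::rnorm(n * n_noise, noise_mean, noise_sd), nrow = n))
  }

  d <- ncol(X)
  feats <- sprintf(paste0("gene%0", nchar(d), "d"), seq_len(d))
  colnames(X) <- feats
  names(contaminated) <- feats[informative][seq_along(contaminated)]
  data <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf(paste0("sample%0", nchar(n), "d"), seq_len(n)),
                   class = y),
    tibble::as_tibble(X))
  structure(
    list(data = data,
         informative_indices = informative,
         informative = feats[informative],
         beta = beta,
         scenario = scenario,
         contaminated = contaminated,
         config = list(scenario = scenario, n = n, d_base = d_base,
                       n_noise = if (scenario == "S1") n_noise else 0L,
                       k_informative = k_informative, a = a, b = b,
                       beta_range = beta_range, outlier_mean = outlier_mean,
                       outlier_spread = outlier_spread, noise_mean = noise_mean,
                       noise_spread = noise_spread, spread = spread,
                       contamination = if (scenario == "S1") contamination else 0,
                       normal_fraction = normal_fraction, seed = seed)),
    class = "wsnr_simulation")
}

draw_labels <- function(p) {
  for (attempt in seq_len(100)) {
    y <- stats::rbinom(length(p), 1, p)
    if (length(unique(y)) == 2) return(y)
  }
  rlang::abort("Label generation produced a single class in 100 attempts.",
    class = "wsnr_simulation_error")
}

#' Fraction of class-1 labels
#'
#' @param x A `wsnr_simulation`, or a data frame with a label column.
#' @param label Label column name when `x` is a data frame.
#' @return The fraction of samples labelled 1, in \[0, 1\].
#' @export
class_balance <- function(x, label = "class") {
  y <- if (inherits(x, "wsnr_simulation")) x$data$class else map_labels(x[[label]])
  mean(y == 1)
}

#' @export
print.wsnr_simulation <- function(x, ...) {
  cat(sprintf("# Simulated two-class expression data (scenario %s)\n", x$scenario))
  cat(sprintf("#  %d samples x %d features, %d planted informative, balance %.2f\n",
              nrow(x$data), ncol(x$data) - 2, length(x$informative_indices),
              class_balance(x)))
  cat("#  planted:", paste(x$informative, collapse = ", "), "\n")
  invisible(x)
}
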