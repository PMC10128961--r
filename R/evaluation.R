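#' Split a dataset into train and test parts
#'
#' Stratified by default: each class contributes `round(train_fraction * n_c)`
#' samples to the training part (clamped so both parts keep at least one
#' sample of the class), so both parts contain both classes.
#'
#' @param data Data frame of samples by features with a label column.
#' @param train_fraction Fraction of samples in the training part, in (0, 1).
#' @param stratified Preserve per-class proportions. Default `TRUE`.
#' @param label Label column name.
#' @param seed Optional seed; the same seed reproduces the same split.
#' @return A list with tibbles `train` and `test` and the integer row
#'   indices `train_indices`, `test_indices` (a disjoint, exhaustive
#'   partition of the rows).
#' @export
split_train_test <- function(data, train_fraction = 0.7, stratified = TRUE,
                             label = "class", seed = NULL) {
  stopifnot(is.data.frame(data))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    rlang::abort("`train_fraction` must lie strictly between 0 and 1.",
      class = "wsnr_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  y <- map_labels(data[[label]])
  if (stratified) {
    if (min(table(y)) < 2) {
      rlang::abort("Stratified split needs at least 2 samples per class.",
        class = "wsnr_input_error")
    }
    # Largest-remainder apportionment: per-class training counts sum to
    # round(train_fraction * n), each class keeps >= 1 sample in each part.
    n_c <- c(sum(y == 0), sum(y == 1))
    quota <- train_fraction * n_c
    n_tr_c <- floor(quota)
    short <- round(train_fraction * n) - sum(n_tr_c)
    if (short > 0) {
      give <- order(-(quota - n_tr_c))[seq_len(min(short, 2))]
      n_tr_c[give] <- n_tr_c[give] + 1L
    }
    n_tr_c <- pmin(pmax(n_tr_c, 1L), n_c - 1L)
    train_idx <- sort(c(sample(which(y == 0), n_tr_c[1]),
                        sample(which(y == 1), n_tr_c[2])))
  } else {
    n_tr <- min(max(round(train_fraction * n), 1L), n - 1L)
    train_idx <- sort(sample.int(n, n_tr))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE],
       train_indices = train_idx, test_indices = test_idx)
}

#' Misclassification rate
#'
#' @param predicted,truth Label vectors of equal length.
#' @return Fraction of mismatches, in \[0, 1\].
#' @export
error_rate <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0) {
    rlang::abort("`predicted` and `truth` must have equal positive length.",
      class = "wsnr_input_error")
  }
  mean(predicted != truth)
}

# Fit the downstream classifier on the selected training features and
# predict the test part. RF: 500 trees, nodesize 1, mtry = floor(sqrt(k))
# ("sqrt") or all k features ("all"). kNN: Euclidean majority vote.
classify_once <- function(Xtr, ytr, Xte, classifier,
                          rf_trees = 500, rf_min_node = 1, knn_k = 5,
                          rf_mtry = c("sqrt", "all")) {
  rf_mtry <- match.arg(rf_mtry)
  ytr_f <- factor(ytr, levels = c(0, 1))
  if (classifier == "rf") {
    mtry <- if (rf_mtry == "sqrt") max(1L, floor(sqrt(ncol(Xtr)))) else ncol(Xtr)
    fit <- randomForest::randomForest(
      x = Xtr, y = ytr_f, ntree = rf_trees, mtry = mtry, nodesize = rf_min_node)
    as.integer(as.character(predict(fit, Xte)))
  } else if (classifier == "knn") {
    as.integer(as.character(class::knn(Xtr, Xte, ytr_f, k = knn_k)))
  } else {
    rlang::abort(paste0("Unknown classifier: '", classifier, "'"),
      class = "wsnr_input_error")
  }
}

#' One repetition of the selection-then-classification protocol
#'
#' Splits the data, scores features on the training part only, keeps the
#' top `k`, fits the downstream classifier on the selected training
#' features and returns the test misclassification rate.
#'
#' @inheritParams split_train_test
#' @param method Scoring method name (see [score_features()]).
#' @param k Number of features to select.
#' @param classifier `"rf"` (random forest, 500 trees, nodesize 1,
#'   `floor(sqrt(k))` candidate features per split) or `"knn"` (5
#'   neighbours, Euclidean).
#' @param cost SVM cost for the SVM-based scorers.
#' @param rf_trees,rf_min_node,knn_k,rf_mtry Classifier settings.
#' @return The test error rate.
#' @export
evaluate_once <- function(data, method, k, classifier = c("rf", "knn"),
                          label = "class", cost = 1, train_fraction = 0.7,
                          stratified = TRUE, seed = NULL,
                          rf_trees = 500, rf_min_node = 1, knn_k = 5,
                          rf_mtry = "sqrt") {
  classifier <- match.arg(classifier)
  parts <- split_train_test(data, train_fraction, stratified, label, seed)
  scores <- score_features(parts$train, method, label = label, cost = cost)
  sel <- selected_features(select_top_k(scores, k))
  tr <- split_xy(parts$train, label)
  te <- split_xy(parts$test, label)
  pred <- classify_once(tr$X[, sel, drop = FALSE], tr$y,
                        te$X[, sel, drop = FALSE], classifier,
                        rf_trees, rf_min_node, knn_k, rf_mtry)
  error_rate(pred, te$y)
}

# Deterministic per-(dataset, repeat) seed stream below 2^31.
derive_seed <- function(seed, ds, r, stage = 0L) {
  (seed + 1000003 * ds + 9973 * stage + r) %% 2147483647
}

#' Repeated-split benchmark of feature-selection methods
#'
#' The core evaluation harness: for each dataset and each of `n_repeats`
#' repetitions, one 70/30 (by default) split is drawn and shared across all
#' methods, K values and classifiers, so method comparisons are paired.
#' Feature scores are computed once per method per repeat on the training
#' part and reused across K and classifiers.
#'
#' @param datasets A data frame, or a named list of data frames.
#' @param methods Scoring methods to compare (see [score_features()]).
#' @param k_values Selection sizes K. Default `c(5, 10, 15)`.
#' @param classifiers Subset of `c("rf", "knn")`.
#' @param n_repeats Number of independent splits. Default 500.
#' @inheritParams evaluate_once
#' @param seed Integer seed for the whole run; fixed seed implies
#'   bit-identical results.
#' @param quiet Suppress per-repeat progress messages. Default `TRUE`.
#' @return A tibble of class `wsnr_benchmark`: one row per (dataset,
#'   method, classifier, k) with `mean_error`, `n_repeats`, `n_failed` and
#'   the per-repeat `errors` list-column.
#' @export
run_benchmark <- function(datasets, methods = c("wsnr", "sigf", "wilcoxon"),
                          k_values = c(5, 10, 15), classifiers = c("rf", "knn"),
                          n_repeats = 500, label = "class", cost = 1,
                          train_fraction = 0.7, stratified = TRUE,
                          rf_trees = 500, rf_min_node = 1, knn_k = 5,
                          rf_mtry = "sqrt", seed = 1, quiet = TRUE) {
  if (is.data.frame(datasets)) datasets <- list(dataset = datasets)
  stopifnot(length(datasets) > 0, n_repeats >= 1)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  classifiers <- match.arg(classifiers, c("rf", "knn"), several.ok = TRUE)

  grid <- tidyr::expand_grid(
    dataset = names(datasets), method = methods,
    classifier = classifiers, k = k_values)
  cells <- stats::setNames(
    rep(list(rep(NA_real_, n_repeats)), nrow(grid)),
    paste(grid$dataset, grid$method, grid$classifier, grid$k, sep = "\r"))

  for (ds_i in seq_along(datasets)) {
    ds_name <- names(datasets)[ds_i]
    data <- as_expression_data(datasets[[ds_i]], label)
    for (r in seq_len(n_repeats)) {
      if (!quiet) rlang::inform(sprintf("[%s] repeat %d/%d", ds_name, r, n_repeats))
      parts <- split_train_test(data, train_fraction, stratified, label,
                                seed = derive_seed(seed, ds_i, r))
      tr <- split_xy(parts$train, label)
      te <- split_xy(parts$test, label)
      for (m_i in seq_along(methods)) {
        scores <- tryCatch(
          score_features(parts$train, methods[m_i], label = label, cost = cost),
          error = function(e) NULL)
        if (is.null(scores)) next
        for (k_i in seq_along(k_values)) {
          if (k_values[k_i] > nrow(scores)) next
          sel <- selected_features(select_top_k(scores, k_values[k_i]))
          Xtr <- tr$X[, sel, drop = FALSE]
          Xte <- te$X[, sel, drop = FALSE]
          for (c_i in seq_along(classifiers)) {
            err <- tryCatch({
              set.seed(derive_seed(seed, ds_i, r,
                                   stage = 100 * m_i + 10 * k_i + c_i))
              pred <- classify_once(Xtr, tr$y, Xte, classifiers[c_i],
                                    rf_trees, rf_min_node, knn_k, rf_mtry)
              error_rate(pred, te$y)
            }, error = function(e) NA_real_)
            key <- paste(ds_name, methods[m_i], classifiers[c_i], k_values[k_i],
                         sep = "\r")
            cells[[key]][r] <- err
          }
        }
      }
    }
  }

  out <- grid |>
    dplyr::mutate(
      errors = unname(cells[paste(.data$dataset, .data$method, .data$classifier,
                                  .data$k, sep = "\r")]),
      mean_error = purrr::map_dbl(.data$errors, ~ mean(.x, na.rm = TRUE)),
      n_repeats = n_repeats,
      n_failed = purrr::map_int(.data$errors, ~ sum(is.na(.x)))) |>
    dplyr::select("dataset", "method", "classifier", "k",
                  "mean_error", "n_repeats", "n_failed", "errors")
  new_benchmark(out, seed = seed,
                config = list(methods = methods, k_values = k_values,
                              classifiers = classifiers, n_repeats = n_repeats,
                              train_fraction = train_fraction,
                              stratified = stratified, cost = cost,
                              rf_trees = rf_trees, rf_min_node = rf_min_node,
                              knn_k = knn_k, rf_mtry = rf_mtry))
}

new_benchmark <- function(tbl, seed = NULL, config = list()) {
  structure(tbl, class = c("wsnr_benchmark", class(tibble::tibble())),
            seed = seed, config = config)
}

#' @export
print.wsnr_benchmark <- function(x, ...) {
  cat("# Repeated-split benchmark:",
      sprintf("%d cell(s), %d repeat(s)\n",
              nrow(x), if (nrow(x)) x$n_repeats[1] else 0))
  NextMethod()
}

#' Monte-Carlo simulation study over fresh synthetic datasets
#'
#' Generates `n_datasets` independent realizations of a simulation scenario
#' (each with its own coefficient draw, labels and — for S1 — contamination)
#' and runs the repeated-split benchmark with `n_repeats` splits on each,
#' pooling the per-repeat errors across realizations. Pooling over fresh
#' realizations rather than re-splitting a single draw keeps the estimate
#' from being dominated by one coefficient vector.
#'
#' @param scenario `"S1"` or `"S2"` (see [simulate_expression()]).
#' @param n_datasets Number of independent simulated datasets. Default 5.
#' @param n_repeats Splits per dataset. Default 20.
#' @inheritParams run_benchmark
#' @param seed Integer seed driving both simulation and splitting.
#' @param ... Passed to [simulate_expression()] (e.g. `n`, `contamination`).
#' @return A pooled `wsnr_benchmark` tibble (dataset column = scenario);
#'   attribute `per_dataset` holds the unpooled result, `simulations` the
#'   generated datasets' ground truth.
#' @export
run_simulation_study <- function(scenario = c("S1", "S2"),
                                 methods = c("wsnr", "sigf", "wilcoxon"),
                                 k_values = c(5, 10, 15),
                                 classifiers = c("rf", "knn"),
                                 n_datasets = 5, n_repeats = 20,
                                 cost = 1, train_fraction = 0.7,
                                 rf_trees = 500, rf_min_node = 1, knn_k = 5,
                                 rf_mtry = "all", seed = 1, quiet = TRUE, ...) {
  scenario <- match.arg(scenario)
  sims <- purrr::map(seq_len(n_datasets), function(i) {
    simulate_expression(scenario, seed = derive_seed(seed, i, 0, stage = 999), ...)
  })
  datasets <- stats::setNames(purrr::map(sims, "data"),
                              sprintf("%s_rep%d", scenario, seq_len(n_datasets)))
  res <- run_benchmark(datasets, methods = methods, k_values = k_values,
                       classifiers = classifiers, n_repeats = n_repeats,
                       cost = cost, train_fraction = train_fraction,
                       rf_trees = rf_trees, rf_min_node = rf_min_node,
                       knn_k = knn_k, rf_mtry = rf_mtry,
                       seed = seed, quiet = quiet)
  pooled <- res |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$method, .data$classifier, .data$k) |>
    dplyr::summarise(
      errors = list(unlist(errors)),
      n_failed = sum(.data$n_failed), .groups = "drop") |>
    dplyr::mutate(dataset = scenario,
                  mean_error = purrr::map_dbl(.data$errors, ~ mean(.x, na.rm = TRUE)),
                  n_repeats = purrr::map_int(.data$errors, length)) |>
    dplyr::select("dataset", "method", "classifier", "k",
                  "mean_error", "n_repeats", "n_failed", "errors")
  out <- new_benchmark(pooled, seed = seed, config = attr(res, "config"))
  attr(out, "per_dataset") <- res
  attr(out, "simulations") <- purrr::map(sims, function(s) {
    s$data <- NULL
    s
  })
  out
}

#' Win-loss summary of a benchmark
#'
#' For each (dataset, classifier) pair, credits the "win" to the method
#' with the lowest mean error in the largest number of K cells (majority
#' rule). Methods tied on the top win count are reported as co-winners and
#' flagged. Total wins per method are attached as the `totals` attribute
#' and shown by `print()`.
#'
#' @param result A `wsnr_benchmark` (or data frame with columns `dataset`,
#'   `method`, `classifier`, `k`, `mean_error`) covering at least two
#'   methods.
#' @return A tibble of class `wsnr_winloss` with one row per (dataset,
#'   classifier): `winners` (list-column), `winner` (collapsed label),
#'   `tie` flag and per-method win counts across K cells.
#' @export
win_loss <- function(result) {
  stopifnot(is.data.frame(result))
  tbl <- tibble::as_tibble(result)[c("dataset", "method", "classifier", "k",
                                     "mean_error")]
  if (dplyr::n_distinct(tbl$method) < 2) {
    rlang::abort("Win-loss summary needs at least two methods.",
      class = "wsnr_input_error")
  }
  best_per_cell <- tbl |>
    dplyr::group_by(.data$dataset, .data$classifier, .data$k) |>
    dplyr::filter(.data$mean_error == min(.data$mean_error)) |>
    dplyr::ungroup()
  out <- best_per_cell |>
    dplyr::count(.data$dataset, .data$classifier, .data$method, name = "cell_wins") |>
    dplyr::group_by(.data$dataset, .data$classifier) |>
    dplyr::summarise(
      winners = list(sort(.data$method[.data$cell_wins == max(.data$cell_wins)])),
      tie = lengths(.data$winners) > 1,
      .groups = "drop") |>
    dplyr::mutate(winner = purrr::map_chr(.data$winners, paste, collapse = "+"))
  totals <- out |>
    tidyr::unnest("winners") |>
    dplyr::count(method = .data$winners, name = "wins") |>
    dplyr::arrange(dplyr::desc(.data$wins))
  structure(out, class = c("wsnr_winloss", class(tibble::tibble())),
            totals = totals)
}

#' @export
print.wsnr_winloss <- function(x, ...) {
  NextMethod()
  cat("\n# Total wins per method:\n")
  print(tibble::as_tibble(attr(x, "totals")))
  invisible(x)
}
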