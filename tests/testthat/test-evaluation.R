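test_that("stratified splits partition the data with apportioned class counts", {
  d <- random_tiny(1, n0 = 5, n1 = 5, d = 3)
  sp <- split_train_test(d, 0.7, stratified = TRUE, seed = 1)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_setequal(c(sp$train_indices, sp$test_indices), 1:10)
  expect_length(intersect(sp$train_indices, sp$test_indices), 0)
  expect_setequal(unique(sp$train$class), 0:1)
  expect_setequal(unique(sp$test$class), 0:1)
  # per-class counts differ by at most 1 from the 70% quota
  expect_true(all(abs(table(sp$train$class) - 3.5) <= 0.5))

  # same seed, same split
  sp2 <- split_train_test(d, 0.7, stratified = TRUE, seed = 1)
  expect_identical(sp$train_indices, sp2$train_indices)

  expect_error(split_train_test(d, 1.0), class = "wsnr_input_error")
  expect_error(split_train_test(d, 0), class = "wsnr_input_error")
  d_single <- d
  d_single$class <- c(0L, rep(1L, 9))
  expect_error(split_train_test(d_single, 0.7, stratified = TRUE),
               class = "wsnr_input_error")
})

test_that("error rate counts mismatches and respects complement symmetry", {
  expect_equal(error_rate(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0)
  expect_equal(error_rate(c(0, 1, 1, 0), c(0, 1, 0, 0)), 0.25)
  pred <- c(0, 1, 0, 1, 1)
  truth <- c(1, 1, 0, 0, 1)
  expect_equal(error_rate(1 - pred, truth), 1 - error_rate(pred, truth))
  expect_error(error_rate(c(0, 1), c(0)), class = "wsnr_input_error")
  # majority-class guessing errs at exactly the minority fraction
  expect_equal(error_rate(rep(1, 5), truth), mean(truth == 0))
})

test_that("selection uses the training part only (no test-set leakage)", {
  set.seed(3)
  sim <- simulate_expression("S2", n = 60, d_base = 30, seed = 3)
  d <- sim$data
  sp <- split_train_test(d, seed = 99)
  sel_ref <- selected_features(select_top_k(snr_scores(sp$train), 5))

  # scramble every feature value in the test rows; the split (same seed,
  # labels unchanged) and hence the training-based selection are unchanged
  d_noisy <- d
  feat <- setdiff(names(d), c("sample_id", "class"))
  d_noisy[sp$test_indices, feat] <- d_noisy[sp$test_indices, sample(feat)]
  sp2 <- split_train_test(d_noisy, seed = 99)
  expect_identical(sp2$train_indices, sp$train_indices)
  sel_noisy <- selected_features(select_top_k(snr_scores(sp2$train), 5))
  expect_identical(sel_noisy, sel_ref)
})

test_that("selecting all features with kNN reduces to plain kNN on the full set", {
  sim <- simulate_expression("S2", n = 50, d_base = 12, seed = 8)
  d <- sim$data
  err <- evaluate_once(d, "snr", k = 12, classifier = "knn", seed = 4)
  sp <- split_train_test(d, seed = 4)
  feat <- setdiff(names(d), c("sample_id", "class"))
  pred <- class::knn(as.matrix(sp$train[feat]), as.matrix(sp$test[feat]),
                     factor(sp$train$class), k = 5)
  expect_equal(err, mean(as.integer(as.character(pred)) != sp$test$class))
})

test_that("a perfectly separating feature yields zero test error", {
  set.seed(10)
  y <- rep(0:1, each = 20)
  d <- tibble::tibble(class = y, marker = y * 10 + stats::rnorm(40, sd = 0.1))
  for (j in 1:8) d[[paste0("noise", j)]] <- stats::rnorm(40)
  err <- evaluate_once(d, "snr", k = 1, classifier = "knn", seed = 2)
  expect_equal(err, 0)
})

test_that("benchmark cells aggregate per-repeat errors and share splits across methods", {
  sim <- simulate_expression("S2", n = 40, d_base = 8, seed = 15)
  res <- run_benchmark(sim$data, methods = "snr", k_values = 3,
                       classifiers = "knn", n_repeats = 2, seed = 5)
  expect_equal(nrow(res), 1)
  expect_length(res$errors[[1]], 2)
  expect_equal(res$mean_error, mean(res$errors[[1]]))
  expect_true(all(unlist(res$errors) >= 0 & unlist(res$errors) <= 1))

  # with k = d every method selects everything; identical shared splits
  # plus the deterministic kNN imply identical per-repeat errors
  res2 <- run_benchmark(sim$data, methods = c("snr", "wilcoxon"), k_values = 8,
                        classifiers = "knn", n_repeats = 3, seed = 6)
  errs <- split(res2$errors, res2$method)
  expect_identical(errs$snr[[1]], errs$wilcoxon[[1]])
})

test_that("benchmarks are bit-reproducible under a fixed seed", {
  sim <- simulate_expression("S1", n = 40, d_base = 10, k_informative = 2,
                             n_noise = 3, seed = 33)
  a <- run_benchmark(sim$data, methods = c("snr", "wsnr"), k_values = c(2, 4),
                     classifiers = c("rf", "knn"), n_repeats = 2, seed = 7)
  b <- run_benchmark(sim$data, methods = c("snr", "wsnr"), k_values = c(2, 4),
                     classifiers = c("rf", "knn"), n_repeats = 2, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("the pooled simulation study stacks per-dataset repeats", {
  st <- run_simulation_study("S2", methods = "snr", k_values = 3,
                             classifiers = "knn", n_datasets = 2,
                             n_repeats = 2, seed = 9,
                             n = 40, d_base = 8)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_repeats, 4L)
  per <- attr(st, "per_dataset")
  expect_equal(sort(unlist(per$errors)), sort(st$errors[[1]]))
  expect_equal(st$mean_error, mean(unlist(per$errors)))
})

test_that("win-loss credits follow majority rule with ties flagged", {
  cells <- function(method, errs) {
    tibble::tibble(dataset = "d1", method = method, classifier = "rf",
                   k = c(5, 10, 15), mean_error = errs)
  }
  # unanimity
  wl <- win_loss(dplyr::bind_rows(cells("A", c(0.1, 0.1, 0.1)),
                                  cells("B", c(0.2, 0.2, 0.2))))
  expect_equal(wl$winner, "A")
  expect_false(wl$tie)
  expect_equal(attr(wl, "totals")$method[1], "A")

  # majority: A best at two of three K
  wl2 <- win_loss(dplyr::bind_rows(cells("A", c(0.1, 0.3, 0.1)),
                                   cells("B", c(0.2, 0.2, 0.2))))
  expect_equal(wl2$winner, "A")

  # complete tie -> co-winners flagged
  wl3 <- win_loss(dplyr::bind_rows(cells("A", c(0.1, 0.2, 0.3)),
                                   cells("B", c(0.1, 0.2, 0.3))))
  expect_true(wl3$tie)
  expect_equal(wl3$winner, "A+B")

  expect_error(win_loss(cells("A", c(0.1, 0.2, 0.3))),
               class = "wsnr_input_error")
})

test_that("benchmark tidiers and plots summarise the result", {
  sim <- simulate_expression("S2", n = 40, d_base = 8, seed = 18)
  res <- run_benchmark(sim$data, methods = c("snr", "wilcoxon"), k_values = 3,
                       classifiers = "knn", n_repeats = 2, seed = 5)
  td <- tidy(res)
  expect_false("errors" %in% names(td))
  g <- glance(res)
  expect_equal(g$n_methods, 2L)
  expect_true(g$best_method %in% c("snr", "wilcoxon"))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(snr_scores(sim$data), top_n = 5)
  expect_s3_class(p2, "ggplot")
})
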