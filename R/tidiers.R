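#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature-score table
#'
#' @param x A `wsnr_scores` object.
#' @param ... Unused.
#' @return A plain tibble with a `method` and `direction` column added.
#' @method tidy wsnr_scores
#' @export
tidy.wsnr_scores <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(method = attr(x, "method"),
                  direction = attr(x, "direction"))
}

#' Tidy a simulated dataset: one row per feature
#'
#' @param x A `wsnr_simulation`.
#' @param ... Unused.
#' @return Tibble with `feature`, `kind` (base/noise), `beta` (NA for
#'   noise columns), `informative` and `n_contaminated` per feature.
#' @method tidy wsnr_simulation
#' @export
tidy.wsnr_simulation <- function(x, ...) {
  feats <- setdiff(names(x$data), c("sample_id", "class"))
  d_base <- x$config$d_base
  tibble::tibble(
    feature = feats,
    kind = rep(c("base", "noise"), c(d_base, length(feats) - d_base)),
    beta = c(x$beta, rep(NA_real_, length(feats) - d_base)),
    informative = feats %in% x$informative,
    n_contaminated = purrr::map_int(feats, ~ length(x$contaminated[[.x]])))
}

#' @rdname tidy.wsnr_simulation
#' @method glance wsnr_simulation
#' @export
glance.wsnr_simulation <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    n = nrow(x$data),
    d = ncol(x$data) - 2L,
    n_informative = length(x$informative_indices),
    n_contaminated_cells = sum(lengths(x$contaminated)),
    class_balance = class_balance(x))
}

#' Tidy a benchmark result
#'
#' @param x A `wsnr_benchmark`.
#' @param ... Unused.
#' @return The per-cell tibble without the per-repeat list-column.
#' @method tidy wsnr_benchmark
#' @export
tidy.wsnr_benchmark <- function(x, ...) {
  tibble::as_tibble(x) |> dplyr::select(-"errors")
}

#' @rdname tidy.wsnr_benchmark
#' @method glance wsnr_benchmark
#' @export
glance.wsnr_benchmark <- function(x, ...) {
  means <- tibble::as_tibble(x) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(overall = mean(.data$mean_error), .groups = "drop")
  tibble::tibble(
    n_datasets = dplyr::n_distinct(x$dataset),
    n_methods = dplyr::n_distinct(x$method),
    n_cells = nrow(x),
    n_repeats = if (nrow(x)) x$n_repeats[1] else 0L,
    best_method = means$method[which.min(means$overall)],
    best_mean_error = min(means$overall))
}
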