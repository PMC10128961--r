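#' Rank features and keep the top K
#'
#' Orders a score vector in its method's direction (descending for
#' higher-is-better scores such as W_SNR, ascending for p-value-based
#' scores) and marks the first `k` features as selected. Ties are broken by
#' ascending feature index (the column order of the scored data), so the
#' ranking is fully deterministic.
#'
#' @param scores A `wsnr_scores` tibble from one of the scorers.
#' @param k Number of features to keep, `1 <= k <= d`.
#' @return A tibble of class `wsnr_selection` with the full ranking:
#'   columns `rank`, `index` (original feature position), `feature`,
#'   `score`, `selected`; attributes `method`, `direction`, `k`.
#' @seealso [selected_features()]
#' @export
select_top_k <- function(scores, k) {
  stopifnot(inherits(scores, "wsnr_scores"))
  d <- nrow(scores)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    rlang::abort("`k` must be a positive integer.", class = "wsnr_input_error")
  }
  if (k > d) {
    rlang::abort(sprintf("`k` (%d) exceeds the number of features (%d).", k, d),
      class = "wsnr_input_error")
  }
  direction <- attr(scores, "direction")
  idx <- seq_len(d)
  key <- if (direction == "higher") -scores$score else scores$score
  ord <- order(key, idx, na.last = TRUE)
  out <- tibble::tibble(
    rank = idx,
    index = ord,
    feature = scores$feature[ord],
    score = scores$score[ord],
    selected = idx <= k)
  structure(out,
            class = c("wsnr_selection", class(tibble::tibble())),
            method = attr(scores, "method"), direction = direction, k = as.integer(k))
}

#' Names of the selected features
#'
#' @param selection A `wsnr_selection` from [select_top_k()].
#' @return Character vector of the top-K feature names, best first.
#' @export
selected_features <- function(selection) {
  stopifnot(inherits(selection, "wsnr_selection"))
  selection$feature[selection$selected]
}

#' @export
print.wsnr_selection <- function(x, ...) {
  cat(sprintf("# Top-%d selection by %s\n", attr(x, "k"), attr(x, "method")))
  NextMethod()
}
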