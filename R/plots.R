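#' Plot a benchmark result
#'
#' Bar chart of mean error rate per method, faceted by classifier and
#' selection size K — the usual way repeated-holdout comparisons of filter
#' methods are displayed.
#'
#' @param object A `wsnr_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wsnr_benchmark
#' @export
autoplot.wsnr_benchmark <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$method, y = .data$mean_error,
                                 fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(ggplot2::vars(.data$classifier),
                        ggplot2::vars(.data$k),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Mean test error rate") +
    ggplot2::theme_minimal()
}

#' Plot the top of a feature-score ranking
#'
#' @param object A `wsnr_scores` object.
#' @param top_n Number of best-ranked features to show. Default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wsnr_scores
#' @export
autoplot.wsnr_scores <- function(object, top_n = 20, ...) {
  sel <- select_top_k(object, min(top_n, nrow(object)))
  tibble::as_tibble(sel) |>
    dplyr::filter(.data$selected) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$feature, -.data$rank),
                                 y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste(attr(object, "method"), "score")) +
    ggplot2::theme_minimal()
}
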