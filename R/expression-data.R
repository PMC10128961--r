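#' Validate a two-class expression data frame
#'
#' The universal input of the package is a data frame with one row per
#' sample: a label column with exactly two distinct values (mapped to 0/1),
#' an optional `sample_id` column, and numeric feature columns for
#' everything else.
#'
#' @param data A data frame of samples by features plus a label column.
#' @param label Name of the label column. Default `"class"`.
#' @param na_action `"error"` rejects missing expression values (default);
#'   `"impute"` replaces them with the feature mean.
#' @return The validated data as a tibble, labels mapped to integer 0/1.
#' @export
as_expression_data <- function(data, label = "class", na_action = c("error", "impute")) {
  na_action <- match.arg(na_action)
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame of samples by features.",
      class = "wsnr_input_error")
  }
  if (!label %in% names(data)) {
    rlang::abort(
      paste0("Label column '", label, "' not found in the data."),
      class = "wsnr_input_error")
  }
  data <- tibble::as_tibble(data)
  y <- map_labels(data[[label]])
  feat_cols <- setdiff(names(data), c(label, "sample_id"))
  if (length(feat_cols) == 0) {
    rlang::abort("No feature columns found.", class = "wsnr_input_error")
  }
  if (anyDuplicated(feat_cols)) {
    rlang::abort("Feature names must be unique.", class = "wsnr_validation_error")
  }
  for (fc in feat_cols) {
    v <- data[[fc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      rlang::abort(
        paste0("Non-numeric expression value in column '", fc, "'",
               if (!is.na(bad)) paste0(", row ", bad) else ""),
        class = "wsnr_parse_error")
    }
    if (anyNA(v)) {
      if (na_action == "error") {
        rlang::abort(
          paste0("Missing expression values in column '", fc,
                 "' (use na_action = \"impute\" to mean-impute)."),
          class = "wsnr_validation_error")
      }
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      data[[fc]] <- v
    }
  }
  if (min(table(y)) < 2) {
    rlang::abort("Each class must contain at least 2 samples.",
      class = "wsnr_validation_error")
  }
  data[[label]] <- y
  data
}

# Map a two-valued label vector to integer 0/1. Values already in {0,1}
# pass through; otherwise the two observed values are sorted (lexicographic
# for character/factor, numeric order otherwise) and mapped in order,
# unless an explicit `levels` vector (length 2, value-for-0 first) is given.
map_labels <- function(y, levels = NULL) {
  if (anyNA(y)) {
    rlang::abort("Label column contains missing values.", class = "wsnr_input_error")
  }
  vals <- sort(unique(y))
  if (length(vals) < 2) {
    rlang::abort("Data contains a single class; two classes are required.",
      class = "wsnr_validation_error")
  }
  if (length(vals) > 2) {
    rlang::abort(
      paste0("Label column has ", length(vals), " distinct values; exactly 2 required."),
      class = "wsnr_input_error")
  }
  if (!is.null(levels)) {
    if (!setequal(levels, vals)) {
      rlang::abort("`levels` must match the two observed label values.",
        class = "wsnr_input_error")
    }
    vals <- levels
  }
  as.integer(y == vals[2])
}

# Internal canonical representation: numeric matrix X (n x d), integer y.
split_xy <- function(data, label = "class") {
  feat_cols <- setdiff(names(data), c(label, "sample_id"))
  X <- as.matrix(data[feat_cols])
  storage.mode(X) <- "double"
  list(
    X = X,
    y = map_labels(data[[label]]),
    feature_names = feat_cols,
    sample_ids = if ("sample_id" %in% names(data)) as.character(data[["sample_id"]])
                 else as.character(seq_len(nrow(data)))
  )
}

#' Read a two-class expression matrix from delimited text
#'
#' Reads a CSV/TSV file into the samples-by-features layout used throughout
#' the package. Files stored genes-in-rows (features as rows, samples as
#' columns, feature identifiers in the first column, the label row named
#' like `label`) are transposed on the way in.
#'
#' @param path Path to a delimited text file with a header row.
#' @param label Name of the label column (or, for `orientation = "genes"`,
#'   the label row). Default `"class"`.
#' @param orientation `"samples"` (rows are samples, default) or `"genes"`
#'   (rows are features).
#' @param delimiter Field delimiter; guessed from the file extension when
#'   `NULL` (`.csv` is comma, anything else tab).
#' @param label_levels Optional length-2 vector giving the label value mapped
#'   to 0 then the value mapped to 1; defaults to sorted order.
#' @param na_action Passed to [as_expression_data()].
#' @return A tibble with columns `sample_id`, the label column (integer 0/1),
#'   and one numeric column per feature.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(class = c("a", "a", "b", "b"), g1 = 1:4, g2 = 4:1),
#'           path, row.names = FALSE)
#' read_expression(path)
read_expression <- function(path, label = "class",
                            orientation = c("samples", "genes"),
                            delimiter = NULL, label_levels = NULL,
                            na_action = c("error", "impute")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path), class = "wsnr_input_error")
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols())
  if (orientation == "genes") {
    raw <- transpose_expression(raw, label)
  }
  if (!label %in% names(raw)) {
    rlang::abort(
      paste0("Label column '", label, "' not found in ", path),
      class = "wsnr_input_error")
  }
  if (!is.null(label_levels)) {
    raw[[label]] <- map_labels(raw[[label]], levels = label_levels)
  }
  if (!"sample_id" %in% names(raw)) {
    raw <- dplyr::mutate(raw, sample_id = sprintf("sample%d", dplyr::row_number()),
                         .before = 1)
  }
  as_expression_data(raw, label = label, na_action = na_action)
}

# Genes-in-rows: first column = feature names (one row holds the labels),
# remaining columns = samples, header = sample ids.
transpose_expression <- function(raw, label) {
  ids <- as.character(raw[[1]])
  if (!label %in% ids) {
    rlang::abort(
      paste0("Label row '", label, "' not found in genes-in-rows file."),
      class = "wsnr_input_error")
  }
  mat <- t(as.matrix(raw[-1]))
  colnames(mat) <- ids
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  out <- dplyr::mutate(out, dplyr::across(-dplyr::all_of(label),
                                          ~ suppressWarnings(as.numeric(.x))))
  dplyr::mutate(out, sample_id = colnames(raw)[-1], .before = 1)
}

#' Write a benchmark result as a wide error-rate table
#'
#' One row per (dataset, K), one column per classifier/method pair, mean
#' error rates printed with three decimals.
#'
#' @param result A benchmark result from [run_benchmark()] or a data frame
#'   with columns `dataset`, `method`, `classifier`, `k`, `mean_error`.
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path) {
  stopifnot(is.data.frame(result))
  if (nrow(result) == 0) {
    rlang::abort("Empty benchmark result.", class = "wsnr_input_error")
  }
  wide <- result |>
    dplyr::mutate(cell = sprintf("%.3f", .data$mean_error),
                  column = paste(.data$classifier, .data$method, sep = "_")) |>
    dplyr::select("dataset", "k", "column", "cell") |>
    tidyr::pivot_wider(names_from = "column", values_from = "cell") |>
    dplyr::arrange(.data$dataset, .data$k)
  readr::write_csv(wide, path)
  invisible(path)
}
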