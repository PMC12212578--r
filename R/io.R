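#' Read and write unit-level datasets
#'
#' Datasets are comma-delimited text with a header; rows are spatial
#' units in the same order as the rows/columns of the weight matrix
#' (unit identity is positional). Named response, covariate and index
#' columns must be numeric.
#'
#' @param path file path.
#' @param y_col,x_cols,u_cols column names to validate; `NULL` skips the
#'   check for that group (defaults validate the `y`/`x*`/`u*` layout
#'   written by [write_dataset()]).
#' @return `read_dataset()` returns a tibble; `write_dataset()` returns
#'   `path` invisibly.
#' @export
read_dataset <- function(path, y_col = "y", x_cols = NULL, u_cols = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(y_col, x_cols, u_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cl in intersect(c(need,
                         grep("^[xu][0-9]+$", names(df), value = TRUE)),
                       names(df))) {
    if (!is.numeric(df[[cl]]))
      stop("column '", cl, "' is not numeric")
  }
  df
}

#' @rdname read_dataset
#' @param data a data frame or `sisar_data` object (only the tabular part
#'   is written; the weight matrix goes through [write_weights()]).
#' @export
write_dataset <- function(data, path) {
  if (inherits(data, "sisar_data")) data <- data$data
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
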