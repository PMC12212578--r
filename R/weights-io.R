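#' Read and write spatial weight matrices
#'
#' Two plain-text formats are supported: Matrix Market coordinate files
#' (`.mtx`, exact weights, via the Matrix package) and GAL contiguity lists.
#' GAL is a neighbour-list format and stores only the binary adjacency
#' pattern: writing a weighted matrix records which entries are nonzero,
#' and reading returns the binary matrix (apply [row_normalize()] to
#' recover a row-standardized matrix built from binary contiguity).
#'
#' @param W a [spatial_weights] object or matrix.
#' @param path file path.
#' @param format `"mtx"` or `"gal"`; guessed from the file extension when
#'   omitted.
#' @return `read_weights()` returns a [spatial_weights] object;
#'   `write_weights()` returns `path` invisibly.
#' @export
write_weights <- function(W, path, format = guess_weights_format(path)) {
  m <- as_weights_matrix(W)
  format <- match.arg(format, c("mtx", "gal"))
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), path)
  } else {
    n <- nrow(m)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(n), con)
    for (i in seq_len(n)) {
      nb <- which(m[i, ] > 0)
      writeLines(paste(i, length(nb)), con)
      writeLines(paste(nb, collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path, format = guess_weights_format(path)) {
  format <- match.arg(format, c("mtx", "gal"))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (nrow(m) != ncol(m)) stop("weight matrix file is not square")
    if (any(m < 0)) stop("negative weight in file")
    m[m == 0] <- 0  # drop explicit zeros (sign of -0)
    return(spatial_weights(m, kind = "custom"))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- scan(text = lines[[1]], what = integer(), quiet = TRUE)
  # plain "n" header or the 4-token "0 n shp id" variant
  n <- if (length(header) >= 2) header[[2]] else header[[1]]
  m <- matrix(0, n, n)
  pos <- 2L
  while (pos <= length(lines)) {
    hd <- scan(text = lines[[pos]], what = integer(), quiet = TRUE)
    if (length(hd) != 2) stop("malformed GAL record header: ", lines[[pos]])
    i <- hd[[1]]; cnt <- hd[[2]]
    if (i < 1 || i > n) stop("GAL unit index out of range: ", i)
    pos <- pos + 1L
    nb <- integer(0)
    if (cnt > 0) {
      nb <- scan(text = lines[[pos]], what = integer(), quiet = TRUE)
      pos <- pos + 1L
    }
    if (length(nb) != cnt) stop("GAL neighbour count mismatch for unit ", i)
    if (any(nb < 1 | nb > n)) stop("GAL neighbour index out of range for unit ", i)
    m[i, nb] <- 1
  }
  spatial_weights(m, kind = "custom")
}

guess_weights_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mtx", "gal")) ext else
    stop("cannot guess weights format from extension '", ext, "'; pass format=")
}
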