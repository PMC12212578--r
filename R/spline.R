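#' Truncated power spline basis
#'
#' The order-p truncated power basis on knots k_1 < ... < k_l is
#' B(t) = (1, t, t^2, ..., t^p, (t - k_1)_+^p, ..., (t - k_l)_+^p),
#' where (x)_+^p equals x^p for x > 0 and 0 otherwise (a term at a knot
#' evaluates to 0, i.e. the boundary uses t <= k). The basis has
#' dimension p + 1 + l and p - 1 continuous derivatives across each knot.
#'
#' @param knots strictly increasing numeric vector of interior knots.
#' @param order spline order p (default 3, cubic).
#' @return An object of class `spline_basis` with elements `knots`,
#'   `order`, `dimension`.
#' @export
spline_basis <- function(knots, order = 3L) {
  knots <- as.numeric(knots)
  if (length(knots) && any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (order < 1) stop("spline order must be a positive integer")
  structure(
    list(knots = knots, order = as.integer(order),
         dimension = as.integer(order) + 1L + length(knots)),
    class = "spline_basis"
  )
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> order %d, %d knot(s), dimension %d\n",
              x$order, length(x$knots), x$dimension))
  invisible(x)
}

#' Order-statistic knot selection
#'
#' Sorts the index values and takes every `step`-th order statistic as a
#' knot (the every-10th-value rule by default). Knots falling on the sample
#' minimum or maximum are dropped: a truncated term at the maximum is
#' identically zero on the sample and one at the minimum duplicates the
#' monomial span, so both would make the basis rank-deficient. Duplicate
#' values are collapsed.
#'
#' @param t numeric vector of index values.
#' @param step spacing between selected order statistics (default 10).
#' @return Numeric vector of strictly increasing interior knots.
#' @export
select_knots <- function(t, step = 10L) {
  step <- as.integer(step)
  if (step < 1) stop("step must be a positive integer")
  if (length(t) <= step) stop("need more than `step` observations to place a knot")
  ts <- sort(t)
  idx <- seq.int(step, length(ts), by = step)
  k <- ts[idx]
  k <- k[k > ts[1] & k < ts[length(ts)]]
  k <- unique(k)
  if (!length(k)) stop("too few distinct values to place interior knots")
  k
}

#' Evaluate the truncated power basis
#'
#' `basis_row()` returns B(t) for a scalar t; `basis_matrix()` stacks
#' B(t_i)' row-wise for a vector, giving the n x (p+1+l) design block.
#'
#' @param t numeric scalar (`basis_row`) or vector (`basis_matrix`).
#' @param basis a [spline_basis] object.
#' @return A numeric vector of length `basis$dimension`, or a matrix with
#'   that many columns.
#' @export
basis_matrix <- function(t, basis) {
  stopifnot(inherits(basis, "spline_basis"))
  t <- as.numeric(t)
  p <- basis$order
  B <- outer(t, 0:p, `^`)
  if (length(basis$knots)) {
    Tr <- outer(t, basis$knots, `-`)
    Tr[Tr <= 0] <- 0
    B <- cbind(B, Tr^p)
  }
  unname(B)
}

#' @rdname basis_matrix
#' @export
basis_row <- function(t, basis) {
  stopifnot(length(t) == 1L)
  drop(basis_matrix(t, basis))
}

#' Evaluate a spline-approximated index function
#'
#' Computes g(t) = B(t)' delta for a coefficient vector delta of length
#' equal to the basis dimension.
#'
#' @param t numeric vector of index values.
#' @param basis a [spline_basis] object.
#' @param delta spline coefficient vector.
#' @return Numeric vector of g values.
#' @export
eval_g <- function(t, basis, delta) {
  delta <- as.numeric(delta)
  if (length(delta) != basis$dimension)
    stop(sprintf("delta has length %d but the basis dimension is %d",
                 length(delta), basis$dimension))
  drop(basis_matrix(t, basis) %*% delta)
}
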