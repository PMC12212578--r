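#' Spatial weight matrix objects
#'
#' A `spatial_weights` object wraps an n x n nonnegative connectivity matrix
#' with a zero diagonal. Row standardization rescales each row with at least
#' one neighbour to sum to 1, so that the spatial lag `W %*% y` is a
#' neighbour average; rows without neighbours are kept with a zero row sum.
#'
#' @param weights numeric n x n matrix, nonnegative, zero diagonal.
#' @param row_standardized logical; has the matrix been row-standardized?
#' @param kind free-text label ("rook", "bishop", "case", "knn", "distance",
#'   "random", "custom").
#'
#' @return An object of class `spatial_weights`: a list with elements
#'   `weights` (base matrix), `n`, `row_standardized`, `kind`.
#' @export
spatial_weights <- function(weights, row_standardized = FALSE, kind = "custom") {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n)
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop("diagonal of a spatial weight matrix must be zero")
  structure(
    list(weights = unname(weights), n = n,
         row_standardized = isTRUE(row_standardized), kind = kind),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat(sprintf("<spatial_weights> %s, n = %d, %d links, %s\n",
              x$kind, x$n, nz,
              if (x$row_standardized) "row-standardized" else "raw"))
  iso <- sum(rowSums(x$weights) == 0)
  if (iso > 0) cat(sprintf("  %d unit(s) with no neighbours\n", iso))
  invisible(x)
}

#' @export
as.matrix.spatial_weights <- function(x, ...) x$weights

#' Total sum of spatial weights
#'
#' The scalar S0 = sum_i sum_j w_ij entering the Moran's I normalization.
#'
#' @param W a [spatial_weights] object or plain matrix.
#' @return A single number.
#' @export
weight_total <- function(W) sum(as_weights_matrix(W))

# Accept either a spatial_weights object or a bare matrix everywhere.
as_weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$weights else as.matrix(W)
}

#' Row-standardize a weight matrix
#'
#' Divides every row with a positive sum by that sum; rows with no
#' neighbours are left as zeros. Idempotent.
#'
#' @param W a [spatial_weights] object or matrix.
#' @return A row-standardized [spatial_weights] object.
#' @export
row_normalize <- function(W) {
  kind <- if (inherits(W, "spatial_weights")) W$kind else "custom"
  m <- as_weights_matrix(W)
  rs <- rowSums(m)
  pos <- rs > 0
  m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
  spatial_weights(m, row_standardized = TRUE, kind = kind)
}

grid_adjacency <- function(h, offsets) {
  n <- h * h
  m <- matrix(0, n, n)
  if (h == 1L) return(m)
  row <- rep(seq_len(h), each = h)   # grid row index of unit i (row-major)
  col <- rep(seq_len(h), times = h)  # grid column index
  for (off in offsets) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= h
    i <- which(ok)
    j <- (r2[ok] - 1L) * h + c2[ok]
    m[cbind(i, j)] <- 1
  }
  m
}

#' Rook contiguity on a square grid
#'
#' Units live on an h x h grid indexed row-major; two units are neighbours
#' iff their cells share an edge (4-neighbourhood).
#'
#' @param h grid side length; the matrix has n = h^2 units.
#' @param standardize row-standardize the binary adjacency (default TRUE).
#' @return A [spatial_weights] object.
#' @export
rook_grid <- function(h, standardize = TRUE) {
  stopifnot(h >= 1)
  m <- grid_adjacency(as.integer(h),
                      list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)))
  w <- spatial_weights(m, kind = "rook")
  if (standardize) row_normalize(w) else w
}

#' Bishop contiguity on a square grid
#'
#' Neighbours are the cells sharing exactly a corner (diagonal
#' 4-neighbourhood).
#'
#' @inheritParams rook_grid
#' @return A [spatial_weights] object.
#' @export
bishop_grid <- function(h, standardize = TRUE) {
  stopifnot(h >= 1)
  m <- grid_adjacency(as.integer(h),
                      list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  w <- spatial_weights(m, kind = "bishop")
  if (standardize) row_normalize(w) else w
}

#' Group-interaction ("districts") weight matrix
#'
#' r equal groups of `m_members` units; every pair within a group interacts
#' with weight 1/(m_members - 1), no interaction across groups. The matrix
#' is row-stochastic by construction.
#'
#' @param r number of groups.
#' @param m_members group size (>= 2).
#' @return A [spatial_weights] object (already row-standardized).
#' @export
case_groups <- function(r = 3, m_members = 75) {
  stopifnot(r >= 1)
  if (m_members < 2) stop("group size m_members must be at least 2")
  block <- matrix(1 / (m_members - 1), m_members, m_members)
  diag(block) <- 0
  m <- kronecker(diag(r), block)
  spatial_weights(m, row_standardized = TRUE, kind = "case")
}

#' k-nearest-neighbour weights from point coordinates
#'
#' Each unit is linked to its k nearest Euclidean neighbours with weight 1;
#' the matrix is then row-normalized (each link weight 1/k). The relation
#' is not symmetric in general. Distance ties are broken by the smaller
#' unit index.
#'
#' @param points n x 2 numeric matrix of coordinates.
#' @param k number of neighbours, 1 <= k < n.
#' @param standardize row-normalize (default TRUE).
#' @return A [spatial_weights] object.
#' @export
knn_points <- function(points, k, standardize = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!all(is.finite(points))) stop("coordinates must be finite")
  if (k < 1) stop("k must be a positive integer")
  if (k >= n) stop("k must be smaller than the number of points")
  d <- as.matrix(stats::dist(points))
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    # order() is stable on ties -> smaller index wins
    nb <- order(di)[seq_len(k)]
    m[i, nb] <- 1
  }
  w <- spatial_weights(m, kind = "knn")
  if (standardize) row_normalize(w) else w
}

#' Inverse-distance weights
#'
#' Dense kernel w_ij = 1/d_ij for i != j, row-standardized; captures global
#' distance-decaying dependence with no cutoff.
#'
#' @param points n x 2 numeric matrix of coordinates; no two points may
#'   coincide.
#' @param standardize row-standardize (default TRUE).
#' @return A [spatial_weights] object.
#' @export
inverse_distance <- function(points, standardize = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  off <- d[upper.tri(d)]
  if (any(off == 0)) stop("coincident points give infinite inverse distance")
  m <- 1 / d
  diag(m) <- 0
  w <- spatial_weights(m, kind = "distance")
  if (standardize) row_normalize(w) else w
}

#' Random (a-spatial) weight matrix
#'
#' Off-diagonal entries are set to 1 independently with probability
#' `density`, then rows with at least one neighbour are standardized.
#' Represents connectivity driven by non-geographic attributes. The default
#' density 4/(n-1) gives expected degree 4, comparable to rook contiguity.
#'
#' @param n number of units (>= 2).
#' @param density link probability in (0, 1].
#' @param seed integer seed; the draw is reproducible.
#' @param standardize row-standardize (default TRUE).
#' @return A [spatial_weights] object. Units left without neighbours are
#'   retained with zero rows and reported via a message.
#' @export
random_weights <- function(n, density = 4 / (n - 1), seed = 1L, standardize = TRUE) {
  stopifnot(n >= 2)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  m <- local_seed(seed, {
    a <- matrix(stats::rbinom(n * n, 1L, density), n, n)
    diag(a) <- 0
    a
  })
  iso <- sum(rowSums(m) == 0)
  if (iso > 0) message(sprintf("random_weights: %d unit(s) drew no neighbours", iso))
  w <- spatial_weights(m, kind = "random")
  if (standardize) row_normalize(w) else w
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
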