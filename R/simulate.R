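#' Regular square-grid coordinates
#'
#' Unit i of an h x h grid (row-major from the origin in the lower-left
#' corner) gets coordinates
#' u_i = (0.5 * ((i-1) mod h), 0.5 * floor((i-1)/h)), i = 1..h^2.
#'
#' @param h grid side length.
#' @return An h^2 x 2 numeric matrix of coordinates.
#' @export
grid_coordinates <- function(h) {
  stopifnot(h >= 1)
  i <- seq_len(h * h) - 1L
  cbind(0.5 * (i %% h), 0.5 * (i %/% h))
}

#' Uniform random coordinates on a disk
#'
#' Draws n points area-uniformly on the disk of radius R centred at the
#' origin (square-root radius transform).
#'
#' @param n number of points.
#' @param R disk radius.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (e.g. inside [simulate_sisar()]).
#' @return An n x 2 numeric matrix of coordinates.
#' @export
disk_coordinates <- function(n, R = 1, seed = NULL) {
  stopifnot(n >= 1, R > 0)
  draw <- function() {
    r <- R * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Draw i.i.d. covariates from a named law
#'
#' Laws: `"unif"` U(-1,1) (the main simulation design), `"unif01"` U(0,1),
#' `"norm"` N(0,1), `"chisq2"` chi-square with 2 df, `"beta22"` Beta(2,2).
#'
#' @param n rows, @param d columns.
#' @param law law name.
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @return An n x d numeric matrix.
#' @export
draw_covariates <- function(n, d, law = "unif", seed = NULL) {
  law <- match.arg(law, c("unif", "unif01", "norm", "chisq2", "beta22"))
  draw <- function() {
    x <- switch(law,
      unif   = stats::runif(n * d, -1, 1),
      unif01 = stats::runif(n * d, 0, 1),
      norm   = stats::rnorm(n * d),
      chisq2 = stats::rchisq(n * d, df = 2),
      beta22 = stats::rbeta(n * d, 2, 2))
    matrix(x, n, d)
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Heterogeneous spatial-correlation field
#'
#' A per-unit autocorrelation coefficient varying smoothly over space:
#' rho_i = amplitude * sin(frequency * (u_i1 + u_i2)). Used to generate
#' data whose spatial dependence strength differs across units, the
#' setting under which a homogeneous-coefficient SAR fit breaks down.
#'
#' @param coordinates n x 2 matrix of unit coordinates.
#' @param amplitude in (-1, 1); |amplitude| >= 1 is rejected since the
#'   reduced form needs the lag operator norm below 1.
#' @param frequency angular frequency.
#' @return Numeric vector of per-unit coefficients, bounded in (-1, 1).
#' @export
sine_rho_field <- function(coordinates, amplitude = 0.8, frequency = 1) {
  if (abs(amplitude) >= 1)
    stop("|amplitude| must be < 1 for a stable spatial process")
  coordinates <- as.matrix(coordinates)
  amplitude * sin(frequency * (coordinates[, 1] + coordinates[, 2]))
}

#' Simulation design for the varying-coefficient spatial lag model
#'
#' Bundles the data-generating process y_i = g(u_i'alpha) sum_j w_ij y_j +
#' x_i'beta + eps_i. The defaults reproduce the main Monte Carlo design:
#' a 15 x 15 grid (n = 225) with row-standardized rook contiguity,
#' alpha = (1/2, sqrt(3)/2), beta = (1, 2), covariates i.i.d. U(-1,1),
#' g(t) = sin(t) and Gaussian errors with variance 1. The irregular
#' alternative scatters n points uniformly on a disk of radius `R` and
#' links each to its `knn_k` nearest neighbours.
#'
#' @param region `"grid"` or `"disk"`.
#' @param h grid side (grid region; n = h^2).
#' @param n number of units (disk region).
#' @param R disk radius.
#' @param knn_k neighbours for the disk k-NN weights.
#' @param alpha index parameter; normalized to unit length.
#' @param beta regression coefficients.
#' @param g index-coefficient function of the scalar index t = u'alpha.
#' @param covariate_law one of the laws of [draw_covariates()].
#' @param sigma2 error variance.
#' @param weights optional [spatial_weights] object overriding the
#'   region's default (rook for grids, k-NN for disks).
#' @return An object of class `sim_design` (a list of the above).
#' @export
sim_design <- function(region = c("grid", "disk"), h = 15L, n = NULL, R = 1,
                       knn_k = 6L, alpha = c(0.5, sqrt(3) / 2), beta = c(1, 2),
                       g = sin, covariate_law = "unif", sigma2 = 1,
                       weights = NULL) {
  region <- match.arg(region)
  stopifnot(sigma2 > 0, R > 0)
  nrm <- sqrt(sum(alpha^2))
  if (nrm == 0) stop("alpha must be nonzero")
  if (abs(nrm - 1) > 1e-12) alpha <- alpha / nrm
  if (region == "grid") n <- as.integer(h)^2 else {
    if (is.null(n)) stop("disk designs need n")
    n <- as.integer(n)
  }
  structure(
    list(region = region, h = as.integer(h), n = n, R = R,
         knn_k = as.integer(knn_k), alpha = alpha, beta = beta, g = g,
         covariate_law = covariate_law, sigma2 = sigma2, weights = weights),
    class = "sim_design"
  )
}

#' Simulate one dataset from the varying-coefficient spatial lag process
#'
#' Draws covariates and errors, forms G = diag(g(u_i'alpha)) (or a
#' supplied per-unit coefficient field), checks that the lag operator GW
#' has spectral radius below 1, and solves the reduced form
#' (I - GW) Y = X beta + eps by a dense linear solve. All randomness
#' comes from `seed`; for disk designs the coordinates and the k-NN weight
#' matrix are redrawn as part of each replication.
#'
#' @param design a [sim_design].
#' @param seed integer seed.
#' @param rho optional per-unit coefficient vector overriding
#'   `g(u'alpha)` (heterogeneous-rho SAR experiments, cf.
#'   [sine_rho_field()]).
#' @return An object of class `sisar_data`: list with `data` (tibble with
#'   columns y, x1..xd, u1..um, g_true, eps), `W` ([spatial_weights]),
#'   `design`, `seed`.
#' @export
simulate_sisar <- function(design, seed = 1L, rho = NULL) {
  stopifnot(inherits(design, "sim_design"))
  local_seed(seed, {
    n <- design$n
    d <- length(design$beta)
    if (design$region == "grid") {
      U <- grid_coordinates(design$h)
      W <- if (is.null(design$weights)) rook_grid(design$h) else design$weights
    } else {
      U <- disk_coordinates(n, design$R)
      W <- if (is.null(design$weights)) knn_points(U, design$knn_k) else design$weights
    }
    if (W$n != n) stop("weight matrix size does not match the design")
    X <- draw_covariates(n, d, design$covariate_law)
    eps <- stats::rnorm(n, sd = sqrt(design$sigma2))
    g_true <- if (is.null(rho)) design$g(drop(U %*% design$alpha)) else {
      if (length(rho) != n) stop("rho must have one entry per unit")
      rho
    }
    Wm <- W$weights
    A <- diag(n) - g_true * Wm          # I - GW, G diagonal
    # ||GW||_inf = max_i |g_i| row-sum bounds the spectral radius; fall back
    # to an eigenvalue check when the cheap bound is not conclusive
    bound <- max(abs(g_true) * rowSums(Wm))
    if (bound >= 1 - 1e-6) {
      sr <- max(Mod(eigen(g_true * Wm, only.values = TRUE)$values))
      if (sr >= 1 - 1e-6)
        stop(sprintf("unstable design: spectral radius of GW is %.6f", sr))
    }
    Y <- solve(A, drop(X %*% design$beta) + eps)
    dat <- tibble::as_tibble(as.data.frame(X, col.names = paste0("x", seq_len(d))))
    names(dat) <- paste0("x", seq_len(d))
    udat <- tibble::as_tibble(as.data.frame(U))
    names(udat) <- paste0("u", seq_len(ncol(U)))
    out <- dplyr::bind_cols(tibble::tibble(y = Y), dat, udat,
                            tibble::tibble(g_true = g_true, eps = eps))
    structure(list(data = out, W = W, design = design, seed = as.integer(seed)),
              class = "sisar_data")
  })
}

#' @export
print.sisar_data <- function(x, ...) {
  cat(sprintf("<sisar_data> %s design, n = %d, seed = %d\n",
              x$design$region, x$design$n, x$seed))
  print(x$data, n = 5)
  invisible(x)
}
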