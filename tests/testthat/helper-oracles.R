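# Independent oracles used across the test files.

# Naive O(n^2) double-loop Moran's I.
moran_brute <- function(y, Wm) {
  n <- length(y)
  z <- y - mean(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + Wm[i, j] * z[i] * z[j]
  (n / sum(Wm)) * num / sum(z^2)
}

# Alternating single-block estimators (coefficients given the other block),
# iterated to a fixed point; the independent oracle for the joint LS stage.
alternating_stage <- function(Y, X, B, lag, iters = 400) {
  S <- lag
  delta <- rep(0, ncol(B))
  beta <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    beta <- qr.coef(qr(X), Y - S * drop(B %*% delta))
    delta <- qr.coef(qr(S * B), Y - drop(X %*% beta))
  }
  list(delta = delta, beta = beta)
}

# Default study design: 15 x 15 grid, rook, alpha = (1/2, sqrt(3)/2),
# beta = (1, 2), U(-1,1) covariates, g = sin, sigma2 = 1.
study_design <- function(...) sim_design(...)

# A noise-free, spline-representable data set: index variables U(-1,1),
# g a cubic polynomial of the index, zero errors.
representable_sim <- function(n = 100, seed = 42) {
  h <- as.integer(sqrt(n))
  stopifnot(h * h == n)
  W <- rook_grid(h)
  g_cubic <- function(t) 0.2 + 0.3 * t - 0.1 * t^3
  alpha <- c(0.6, 0.8)
  set.seed(seed)
  U <- matrix(stats::runif(2 * n, -1, 1), n, 2)
  X <- matrix(stats::runif(2 * n, -1, 1), n, 2)
  beta <- c(1, 2)
  g <- g_cubic(drop(U %*% alpha))
  Y <- solve(diag(n) - g * W$weights, drop(X %*% beta))
  list(Y = Y, X = X, U = U, W = W, alpha = alpha, beta = beta,
       g = g, g_fun = g_cubic,
       data = tibble::tibble(y = Y, x1 = X[, 1], x2 = X[, 2],
                             u1 = U[, 1], u2 = U[, 2]))
}
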