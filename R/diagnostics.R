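#' Global Moran's I
#'
#' I = (n / S0) * sum_ij w_ij (y_i - ybar)(y_j - ybar) / sum_i (y_i - ybar)^2,
#' with S0 the total sum of weights. Positive values indicate that
#' neighbouring units carry similar values; the expectation under no
#' autocorrelation is -1/(n-1).
#'
#' @param y numeric vector (non-constant).
#' @param W a [spatial_weights] object or matrix with positive total weight.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(y, W) {
  Wm <- as_weights_matrix(W)
  n <- length(y)
  stopifnot(nrow(Wm) == n)
  s0 <- sum(Wm)
  if (s0 <= 0) stop("the weight matrix has no links")
  z <- y - mean(y)
  den <- sum(z^2)
  if (den == 0) stop("y is constant; Moran's I is undefined")
  (n / s0) * drop(crossprod(z, Wm %*% z)) / den
}

#' Permutation inference for Moran's I
#'
#' Random-permutation test: y is shuffled across the units `n_perm` times
#' and the one-sided (positive autocorrelation) p-value is
#' (1 + #\{I_perm >= I_obs\}) / (n_perm + 1). The analytical expectation
#' -1/(n-1), the randomization-assumption variance (closed-form
#' permutation moments, including the kurtosis term) and the z-score are
#' reported alongside.
#'
#' @param y numeric vector.
#' @param W a [spatial_weights] object or matrix.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `moran_test`: list with `I`, `expected_I`,
#'   `variance`, `z`, `p`, `n_perm`, `alternative`, `perm` (the permuted
#'   statistics).
#' @export
moran_permutation <- function(y, W, n_perm = 999L, seed = 1L,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  Wm <- as_weights_matrix(W)
  n <- length(y)
  obs <- morans_i(y, Wm)
  # vectorized permutation null: I = (n/S0) z'Wz / z'z for shuffled z
  z <- y - mean(y)
  perm <- local_seed(seed, {
    P <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
    (n / sum(Wm)) * colSums(P * (Wm %*% P)) / sum(z^2)
  })
  p <- if (alternative == "greater") {
    (1 + sum(perm >= obs)) / (n_perm + 1)
  } else {
    e <- -1 / (n - 1)
    (1 + sum(abs(perm - e) >= abs(obs - e))) / (n_perm + 1)
  }
  mom <- moran_randomization_moments(y, Wm)
  structure(
    list(I = obs, expected_I = mom$expectation, variance = mom$variance,
         z = (obs - mom$expectation) / sqrt(mom$variance), p = p,
         n_perm = as.integer(n_perm), alternative = alternative, perm = perm),
    class = "moran_test"
  )
}

# Closed-form moments of Moran's I under the randomization assumption.
moran_randomization_moments <- function(y, Wm) {
  n <- length(y)
  z <- y - mean(y)
  s0 <- sum(Wm)
  s1 <- sum((Wm + t(Wm))^2) / 2
  s2 <- sum((rowSums(Wm) + colSums(Wm))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  e <- -1 / (n - 1)
  v <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
          b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - e^2
  list(expectation = e, variance = v)
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, variance %.4f, z = %.2f)\n",
              x$I, x$expected_I, x$variance, x$z))
  cat(sprintf("  permutation p-value (%s, %d permutations): %.4g\n",
              x$alternative, x$n_perm, x$p))
  invisible(x)
}

#' Moran scatter decomposition
#'
#' Per-unit deviation z_i = y_i - ybar and spatial lag of deviations
#' lag_i = sum_j w_ij z_j, with the quadrant classification HH / LH / LL /
#' HL by the signs of (z_i, lag_i). Zero deviations or lags are assigned
#' to the "high" side (HH convention). With a row-standardized W the
#' slope of lag on deviation equals Moran's I.
#'
#' @param y numeric vector.
#' @param W a [spatial_weights] object or matrix.
#' @return A tibble with columns `unit`, `deviation`, `lag`, `quadrant`.
#' @export
moran_scatter <- function(y, W) {
  Wm <- as_weights_matrix(W)
  z <- y - mean(y)
  if (all(z == 0)) stop("y is constant; the Moran scatter is undefined")
  lag <- drop(Wm %*% z)
  quadrant <- dplyr::case_when(
    z >= 0 & lag >= 0 ~ "HH",
    z < 0 & lag >= 0 ~ "LH",
    z < 0 & lag < 0 ~ "LL",
    TRUE ~ "HL")
  tibble::tibble(unit = seq_along(y), deviation = z, lag = lag,
                 quadrant = factor(quadrant, levels = c("HH", "LH", "LL", "HL")))
}

#' Lagrange multiplier tests for spatial dependence
#'
#' Score tests built from OLS residuals of y on X. `lm_lag()` tests the
#' null of no spatial lag effect (rho = 0); `lm_error()` tests no spatial
#' autocorrelation in the errors (lambda = 0). Both statistics are
#' asymptotically chi-square with 1 degree of freedom under their nulls.
#'
#' @param y response vector.
#' @param X covariate matrix (an intercept column is prepended unless
#'   `intercept = FALSE`).
#' @param W a [spatial_weights] object or matrix (nonzero).
#' @param intercept include an intercept in the OLS regression.
#' @return An object of class `lm_test`: list with `statistic`, `p`,
#'   `test`.
#' @export
lm_lag <- function(y, X, W, intercept = TRUE) {
  lm_spatial_score(y, X, W, intercept, test = "lag")
}

#' @rdname lm_lag
#' @export
lm_error <- function(y, X, W, intercept = TRUE) {
  lm_spatial_score(y, X, W, intercept, test = "error")
}

lm_spatial_score <- function(y, X, W, intercept, test) {
  Wm <- as_weights_matrix(W)
  if (sum(Wm != 0) == 0) stop("the weight matrix is identically zero")
  X <- as.matrix(X)
  if (intercept) X <- cbind(1, X)
  n <- length(y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate matrix")
  e <- qr.resid(qx, y)
  s2 <- sum(e^2) / n
  Tw <- sum(Wm * Wm) + sum(Wm * t(Wm))   # tr(W^2 + W'W) = tr(WW) + tr(W'W)
  stat <- if (test == "error") {
    (drop(crossprod(e, Wm %*% e)) / s2)^2 / Tw
  } else {
    b <- qr.coef(qx, y)
    wxb <- drop(Wm %*% (X %*% b))
    J <- (sum(qr.resid(qx, wxb)^2) / s2 + Tw)
    (drop(crossprod(e, Wm %*% y)) / s2)^2 / J
  }
  structure(list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 test = test), class = "lm_test")
}

#' @export
print.lm_test <- function(x, ...) {
  cat(sprintf("LM-%s test: statistic = %.4f, p = %.4g (chi-square, 1 df)\n",
              x$test, x$statistic, x$p))
  invisible(x)
}
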