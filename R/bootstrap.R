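#' Residual bootstrap for a varying-coefficient spatial lag fit
#'
#' An extension beyond the core estimator: the reference evaluation of
#' this model reports only Monte Carlo dispersion, not asymptotic
#' standard errors, so uncertainty on a single dataset is quantified by
#' a nonparametric residual bootstrap. Centred residuals are resampled
#' with replacement and responses are regenerated through the reduced
#' form Y* = (I - G_hat W)^{-1} (X beta_hat + eps*), treating the fitted
#' per-unit lag strengths as the truth; the model is refit to every
#' pseudo-sample.
#'
#' @param fit a `sisar_fit`.
#' @param data the data (data frame or `sisar_data`) the model was fit to.
#' @param weights the [spatial_weights] used for the fit (defaults to the
#'   simulated matrix when `data` is a `sisar_data`).
#' @param nboot number of bootstrap replicates.
#' @param seed integer seed.
#' @param ... passed on to [sisar()] for the refits.
#' @return A tibble with columns `term`, `estimate`, `se_boot` for the
#'   index and regression parameters.
#' @export
sisar_bootstrap <- function(fit, data, weights = NULL, nboot = 100L,
                            seed = 1L, ...) {
  stopifnot(inherits(fit, "sisar_fit"))
  if (inherits(data, "sisar_data")) {
    if (is.null(weights)) weights <- data$W
    data <- data$data
  }
  if (!inherits(weights, "spatial_weights")) weights <- spatial_weights(weights)
  df <- as.data.frame(data)
  X <- as.matrix(df[fit$x_cols])
  n <- fit$n
  Wm <- weights$weights
  g_stable <- pmin(pmax(fit$g_hat, -1 + 1e-6), 1 - 1e-6)  # keep I - GW invertible
  A <- diag(n) - g_stable * Wm
  mu <- drop(X %*% unname(fit$beta))
  res <- fit$y - fitted(fit)
  res <- res - mean(res)
  draws <- local_seed(seed, {
    purrr::map(seq_len(nboot), function(b) {
      ystar <- solve(A, mu + sample(res, n, replace = TRUE))
      dfb <- df
      dfb[[fit$y_col]] <- ystar
      fb <- tryCatch(
        suppressWarnings(sisar(dfb, weights, y_col = fit$y_col,
                               x_cols = fit$x_cols, u_cols = fit$u_cols, ...)),
        error = function(e) NULL)
      if (is.null(fb)) NULL else c(fb$alpha, unname(fb$beta))
    })
  })
  est <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (is.null(est) || nrow(est) < 2) stop("bootstrap refits failed")
  tibble::tibble(
    term = c(paste0("alpha", seq_along(fit$alpha)), fit$x_cols),
    estimate = c(fit$alpha, unname(fit$beta)),
    se_boot = apply(est, 2, stats::sd))
}
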