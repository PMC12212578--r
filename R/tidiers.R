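#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a varying-coefficient spatial lag fit
#'
#' One row per parameter: the index-direction components (`alpha1..m`)
#' and the regression coefficients.
#'
#' @param x a `sisar_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`.
#' @method tidy sisar_fit
#' @export
tidy.sisar_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("alpha", seq_along(x$alpha)), names(x$beta)),
    estimate = c(x$alpha, unname(x$beta)))
}

#' @rdname tidy.sisar_fit
#' @method glance sisar_fit
#' @export
glance.sisar_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, loss = x$loss, iterations = x$iterations,
                 converged = x$converged, n = x$n,
                 df = x$basis$dimension + length(x$beta),
                 g_min = min(x$g_hat), g_max = max(x$g_hat))
}

#' Tidy a homogeneous SAR fit
#'
#' @param x a `sar_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`.
#' @method tidy sar_fit
#' @export
tidy.sar_fit <- function(x, ...) {
  tibble::tibble(term = c("rho", names(x$beta)),
                 estimate = c(x$rho, unname(x$beta)))
}

#' @rdname tidy.sar_fit
#' @method glance sar_fit
#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, sigma2 = x$sigma2, loglik = x$loglik,
                 method = x$method, n = x$n)
}

#' Tidy a Moran permutation test
#'
#' @param x a `moran_test`.
#' @param ... unused.
#' @return A one-row tibble mirroring the usual Moran's I report columns.
#' @method tidy moran_test
#' @export
tidy.moran_test <- function(x, ...) {
  tibble::tibble(moran_i = x$I, expected_i = x$expected_I,
                 variance = x$variance, z = x$z, p_value = x$p,
                 n_perm = x$n_perm, alternative = x$alternative)
}

#' Tidy an LM spatial dependence test
#'
#' @param x an `lm_test`.
#' @param ... unused.
#' @return A one-row tibble with `test`, `statistic`, `p_value`.
#' @method tidy lm_test
#' @export
tidy.lm_test <- function(x, ...) {
  tibble::tibble(test = paste0("LM-", x$test), statistic = x$statistic,
                 p_value = x$p)
}

#' Tidy a Monte Carlo experiment
#'
#' @param x an `mc_result`.
#' @param ... unused.
#' @return The per-parameter metrics tibble (parameter, true_value,
#'   estimate, se, bias, mse, nmc).
#' @method tidy mc_result
#' @export
tidy.mc_result <- function(x, ...) x$table

#' @rdname tidy.mc_result
#' @method glance mc_result
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, nmc = x$nmc, failures = x$failures,
                 region = x$design$region, n = x$design$n)
}
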