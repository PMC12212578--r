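#' Monte Carlo evaluation metrics
#'
#' For replicated estimates theta_hat_1..theta_hat_nmc of a parameter
#' theta: S.E. = sqrt(mean((theta_hat - mean)^2)) (population 1/nmc
#' divisor), Bias = |mean - theta|, MSE = mean((theta_hat - theta)^2).
#' Under these conventions MSE = S.E.^2 + Bias^2 exactly.
#'
#' @param estimates numeric vector of replicated estimates.
#' @param true_value the true parameter (may be `NA` when no single truth
#'   exists; bias and mse are then `NA`).
#' @return A one-row tibble with columns `estimate` (the Monte Carlo
#'   mean), `se`, `bias`, `mse`, `nmc`.
#' @export
mc_metrics <- function(estimates, true_value) {
  if (!length(estimates)) stop("no estimates supplied")
  m <- mean(estimates)
  se <- sqrt(mean((estimates - m)^2))
  if (is.na(true_value)) {
    bias <- NA_real_; mse <- NA_real_
  } else {
    bias <- abs(m - true_value)
    mse <- mean((estimates - true_value)^2)
  }
  tibble::tibble(estimate = m, se = se, bias = bias, mse = mse,
                 nmc = length(estimates))
}

#' Run a replicated simulate-and-fit experiment
#'
#' Simulates `nmc` datasets from `design` (replication r uses seed
#' `base_seed + r`), fits the chosen estimator to each, and tabulates the
#' Monte Carlo mean, S.E., bias and MSE of every parameter. Replications
#' whose fit fails or does not converge are excluded with a warning; if
#' they exceed 5% of `nmc` the experiment errors. The whole experiment
#' is a pure function of (design, nmc, base_seed).
#'
#' @param design a [sim_design].
#' @param estimator `"sisar"` (the varying-coefficient model) or `"sar"`
#'   (homogeneous baseline).
#' @param nmc number of replications.
#' @param base_seed integer; replication seeds are `base_seed + 1..nmc`.
#' @param ... passed on to [sisar()] or [fit_sar()].
#' @return An object of class `mc_result`: list with `table` (tibble:
#'   parameter, true_value, estimate, se, bias, mse), `draws` (nmc_ok x
#'   n_par matrix of per-replication estimates), `design`, `estimator`,
#'   `nmc`, `seeds`, `failures`.
#' @export
run_experiment <- function(design, estimator = c("sisar", "sar"), nmc = 300L,
                           base_seed = 1L, ...) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(design, "sim_design"))
  d <- length(design$beta)
  m <- length(design$alpha)
  seeds <- base_seed + seq_len(nmc)
  one_rep <- function(seed) {
    sim <- simulate_sisar(design, seed = seed)
    if (estimator == "sisar") {
      f <- sisar(sim, ...)
      if (!f$converged) return(NULL)
      c(stats::setNames(f$alpha, paste0("alpha", seq_len(m))),
        stats::setNames(unname(f$beta), paste0("beta", seq_len(d))),
        sigma2 = f$sigma2)
    } else {
      f <- fit_sar(sim, ...)
      c(rho = f$rho,
        stats::setNames(unname(f$beta), paste0("beta", seq_len(d))),
        sigma2 = f$sigma2)
    }
  }
  draws <- purrr::map(seeds, function(s) {
    tryCatch(one_rep(s), error = function(e) NULL)
  })
  ok <- !vapply(draws, is.null, logical(1))
  failures <- sum(!ok)
  if (failures > 0) {
    if (failures / nmc >= 0.05)
      stop(sprintf("%d/%d replications failed or did not converge", failures, nmc))
    warning(sprintf("%d/%d replications excluded (failed or non-converged)",
                    failures, nmc))
  }
  est <- do.call(rbind, draws[ok])
  truth <- if (estimator == "sisar") {
    c(design$alpha, design$beta, design$sigma2)
  } else {
    c(NA_real_, design$beta, design$sigma2)
  }
  table <- purrr::map_dfr(seq_len(ncol(est)), function(j) {
    dplyr::bind_cols(
      tibble::tibble(parameter = colnames(est)[j], true_value = truth[j]),
      mc_metrics(est[, j], truth[j]))
  })
  structure(list(table = table, draws = est, design = design,
                 estimator = estimator, nmc = as.integer(nmc),
                 seeds = seeds, failures = failures),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo experiment: %s estimator, %d replications (%d excluded)\n",
              x$estimator, x$nmc, x$failures))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Histogram and normal Q-Q summary of Monte Carlo draws
#'
#' Deterministic Freedman-Diaconis binning of the replicated estimates of
#' one parameter, plus ordered (theoretical, sample) quantile pairs
#' against the standard normal law for the standardized draws. Plot-ready
#' data; rendering is left to the caller (or [ggplot2::autoplot()]).
#'
#' @param result an `mc_result`.
#' @param parameter parameter name (a column of `result$draws`).
#' @return List with `histogram` (tibble: lower, upper, mid, count) and
#'   `qq` (tibble: theoretical, sample).
#' @export
estimate_distribution_summary <- function(result, parameter) {
  stopifnot(inherits(result, "mc_result"))
  if (!parameter %in% colnames(result$draws))
    stop("unknown parameter: ", parameter)
  x <- result$draws[, parameter]
  if (length(x) < 20) stop("need at least 20 draws for a distribution summary")
  if (stats::sd(x) == 0) stop("degenerate (constant) draws")
  iqr <- stats::IQR(x)
  width <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else diff(range(x)) / 10
  breaks <- seq(min(x), max(x) + width, by = width)
  counts <- table(cut(x, breaks, include.lowest = TRUE, right = FALSE))
  histogram <- tibble::tibble(
    lower = breaks[-length(breaks)], upper = breaks[-1],
    mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = as.integer(counts))
  zs <- sort((x - mean(x)) / stats::sd(x))
  qq <- tibble::tibble(
    theoretical = stats::qnorm(stats::ppoints(length(zs))),
    sample = zs)
  list(histogram = histogram, qq = qq)
}
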