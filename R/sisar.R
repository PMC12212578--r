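#' Spatial instruments for the endogenous lag
#'
#' The spatial lag WY is correlated with the model error (endogeneity of
#' the reduced form), so it is instrumented by the exogenous block
#' \[X, WX, W^2 X, WU, W^2 U\]. Collinear columns are dropped greedily
#' left-to-right by Gram-Schmidt with relative tolerance 1e-10.
#'
#' @param X n x d covariate matrix.
#' @param W a [spatial_weights] object or matrix.
#' @param U n x m index-variable matrix.
#' @return A list with `Q` (n x q instrument matrix, full column rank) and
#'   `kept` (provenance labels of the retained columns).
#' @export
build_instruments <- function(X, W, U) {
  X <- as.matrix(X); U <- as.matrix(U)
  Wm <- as_weights_matrix(W)
  WX <- Wm %*% X; WU <- Wm %*% U
  C <- cbind(X, WX, Wm %*% WX, WU, Wm %*% WU)
  labs <- c(paste0("x", seq_len(ncol(X))),
            paste0("Wx", seq_len(ncol(X))),
            paste0("W2x", seq_len(ncol(X))),
            paste0("Wu", seq_len(ncol(U))),
            paste0("W2u", seq_len(ncol(U))))
  tol <- 1e-10
  norms <- sqrt(colSums(C^2))
  scale_ref <- max(norms)
  keep <- integer(0)
  Qo <- matrix(0, nrow(C), 0)   # orthonormal basis of kept columns
  for (j in seq_len(ncol(C))) {
    v <- C[, j]
    nv <- norms[j]
    if (nv <= tol * scale_ref) next
    r <- v - Qo %*% crossprod(Qo, v)
    # re-orthogonalize once for numerical safety
    r <- r - Qo %*% crossprod(Qo, r)
    if (sqrt(sum(r^2)) > tol * nv) {
      keep <- c(keep, j)
      Qo <- cbind(Qo, r / sqrt(sum(r^2)))
    }
  }
  if (length(keep) < ncol(X))
    stop("insufficient instruments: candidate block has rank below the covariate count")
  list(Q = C[, keep, drop = FALSE], kept = labs[keep])
}

#' First 2SLS stage: project the spatial lag onto the instruments
#'
#' Returns the least-squares projection of WY onto the column space of Q
#' (computed by QR, never by an explicit normal-equation inverse).
#'
#' @param Q instrument matrix (full column rank).
#' @param W a [spatial_weights] object or matrix.
#' @param Y response vector.
#' @return Fitted spatial lag vector (length n).
#' @export
first_stage <- function(Q, W, Y) {
  WY <- drop(as_weights_matrix(W) %*% Y)
  qrQ <- qr(Q)
  if (qrQ$rank < ncol(Q)) stop("instrument matrix is rank deficient")
  drop(qr.fitted(qrQ, WY))
}

#' Second stage: joint spline/regression coefficients
#'
#' With S = diag(wy_hat) the model Y = S B delta + X beta + e is linear in
#' (delta, beta); the joint least-squares minimizer is the exact fixed
#' point of alternating the two single-block estimators. Solved through a
#' column-equilibrated QR decomposition (the truncated power basis is
#' ill-conditioned; no explicit inverse is ever formed).
#'
#' @param Y response vector.
#' @param X n x d covariate matrix.
#' @param B n x (p+1+l) spline basis matrix.
#' @param wy_hat the spatial lag vector conditioned on (the first-stage
#'   fitted lag, or the observed lag for the profiling objective).
#' @return List with `delta`, `beta`, `fitted`, `rss`.
#' @export
second_stage <- function(Y, X, B, wy_hat) {
  X <- as.matrix(X)
  D <- cbind(wy_hat * B, X)
  scl <- sqrt(colSums(D^2))
  if (any(scl == 0)) stop("unidentifiable coefficients: zero column in the stacked design")
  Ds <- sweep(D, 2, scl, `/`)
  qrD <- qr(Ds)
  if (qrD$rank < ncol(Ds)) stop("rank-deficient second-stage design")
  coef <- qr.coef(qrD, Y) / scl
  k <- ncol(B)
  fitted <- drop(D %*% coef)
  list(delta = coef[seq_len(k)], beta = coef[-seq_len(k)],
       fitted = fitted, rss = sum((Y - fitted)^2))
}

#' Instrumented (2SLS) coefficient stage
#'
#' Solves the instrumental-variable normal equations for the model
#' Y = diag(WY) B delta + X beta + e, in which the endogenous block
#' diag(WY) B is instrumented column-wise by diag(WY_hat) B (the
#' first-stage fitted lag in place of the observed one):
#' theta_hat solves Zhat' Z theta = Zhat' Y with Z = \[diag(WY) B, X\] and
#' Zhat = \[diag(WY_hat) B, X\]. Because the observed-lag design appears
#' in the moment conditions, the estimator is exactly unbiased on
#' noise-free data and removes the simultaneity bias of the plain
#' least-squares stage on noisy data.
#'
#' Two numerical safeguards keep weakly instrumented directions from
#' destabilizing the solution. First, the moment system is solved as a
#' correction to the least-squares coefficients through a truncated
#' singular value decomposition: directions of the normal matrix with
#' relative singular value below `tol` carry no instrument information
#' (they arise in tail spline terms supported on a handful of units) and
#' are left at their least-squares values. Second, because the
#' least-squares residual is orthogonal to the design, the corrected
#' residual sum of squares is exactly RSS_ls + s^2 ||Z delta_theta||^2
#' for a step size s, so the correction is damped (s < 1) whenever it
#' would push the RSS above `rss_cap` times the least-squares RSS — a
#' trust-region-style limit far above the size of a typical correction.
#' On noise-free data the correction is identically zero and the exact
#' coefficients are returned.
#'
#' @inheritParams second_stage
#' @param wy observed spatial lag W Y.
#' @param wy_hat first-stage fitted spatial lag.
#' @param tol relative singular-value cutoff for the IV correction.
#' @param rss_cap maximum ratio of corrected to least-squares RSS.
#' @return List with `delta`, `beta`, `fitted` (using the observed lag),
#'   `rss`.
#' @export
second_stage_iv <- function(Y, X, B, wy, wy_hat, tol = 1e-6, rss_cap = 3) {
  X <- as.matrix(X)
  ls <- second_stage(Y, X, B, wy)
  k <- ncol(B)
  theta_ls <- c(ls$delta, ls$beta)
  Z <- cbind(wy * B, X)
  Zh <- cbind(wy_hat * B, X)
  scl <- sqrt(colSums(Z^2))
  Zs <- sweep(Z, 2, scl, `/`)
  A <- crossprod(Zh, Zs)
  r <- drop(crossprod(Zh, Y - ls$fitted))
  sv <- svd(A)
  keep <- sv$d >= tol * sv$d[1]
  corr <- drop(sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], r) / sv$d[keep])) / scl
  # exact damped step: rss(s) = rss_ls + s^2 ||Z corr||^2
  zc2 <- sum((Z %*% corr)^2)
  s_max2 <- (rss_cap - 1) * ls$rss
  s <- if (zc2 > s_max2 && zc2 > 0) sqrt(s_max2 / zc2) else 1
  coef <- theta_ls + s * corr
  fitted <- drop(Z %*% coef)
  list(delta = coef[seq_len(k)], beta = coef[-seq_len(k)],
       fitted = fitted, rss = sum((Y - fitted)^2))
}

alpha_from_phi <- function(phi) {
  s <- sum(phi^2)
  c(sqrt(max(0, 1 - s)), phi)
}

# Everything that does not depend on alpha, computed once per fit.
profile_context <- function(Y, X, U, W, order = 3L, knot_step = 10L) {
  inst <- build_instruments(X, W, U)
  wy <- drop(as_weights_matrix(W) %*% Y)
  wy_hat <- first_stage(inst$Q, W, Y)
  list(Y = Y, X = as.matrix(X), U = as.matrix(U), W = W,
       order = as.integer(order), knot_step = as.integer(knot_step),
       wy = wy, wy_hat = wy_hat, instruments = inst$kept,
       penalty = 1e12 * (1 + sum(Y^2)))
}

# Coefficient stage at a given index direction; NULL on failure.
# mode "ls": least squares conditioning on the observed lag (the profiling
# objective for alpha); mode "iv": instrumented normal equations (the final
# coefficient estimates).
stage_at_alpha <- function(alpha, ctx, mode = c("ls", "iv")) {
  mode <- match.arg(mode)
  t <- drop(ctx$U %*% alpha)
  basis <- tryCatch(spline_basis(select_knots(t, ctx$knot_step), ctx$order),
                    error = function(e) NULL)
  if (is.null(basis)) return(NULL)
  B <- basis_matrix(t, basis)
  st <- tryCatch(
    if (mode == "ls") second_stage(ctx$Y, ctx$X, B, ctx$wy)
    else second_stage_iv(ctx$Y, ctx$X, B, ctx$wy, ctx$wy_hat),
    error = function(e) NULL)
  if (is.null(st)) return(NULL)
  c(st, list(t = t, basis = basis, B = B))
}

#' Profile loss over the index direction
#'
#' Maps the free parameter phi to alpha = (sqrt(1-||phi||^2), phi),
#' rebuilds the index, knots and spline basis at that direction,
#' concentrates out (delta, beta) by the joint second stage conditioning
#' on the observed spatial lag, and returns the residual sum of squares.
#' Failures (rank deficiency, ||phi|| > 1) return a large finite penalty
#' so derivative-based optimizers stay well-behaved.
#'
#' @param phi free index parameter (length m - 1, ||phi|| <= 1).
#' @param ctx context from the internal profiling setup; see [sisar()].
#' @return Scalar loss.
#' @export
profile_loss <- function(phi, ctx) {
  s <- sum(phi^2)
  if (s > 1) return(ctx$penalty * (1 + s))
  st <- stage_at_alpha(alpha_from_phi(phi), ctx)
  if (is.null(st)) return(ctx$penalty)
  st$rss
}

#' Initial index direction
#'
#' For m = 2 a deterministic grid search over phi in \{-1 + 2j/J\},
#' j = 0..J; ties break to the smaller phi. For m > 2, the best of
#' `n_starts` seeded random unit directions with alpha_1 >= 0.
#'
#' @param ctx profiling context.
#' @param grid_J grid resolution for m = 2 (default 40).
#' @param n_starts random starts for m > 2.
#' @param seed seed for the random multistart.
#' @return List with `phi`, `alpha`, `loss`.
#' @export
initial_alpha <- function(ctx, grid_J = 40L, n_starts = 20L, seed = 1L) {
  m <- ncol(ctx$U)
  if (m == 2L) {
    phis <- -1 + 2 * (0:grid_J) / grid_J
    losses <- vapply(phis, function(p) profile_loss(p, ctx), numeric(1))
    best <- which.min(losses)  # first minimum -> smaller phi on ties
    phi <- phis[best]
  } else {
    cand <- local_seed(seed, {
      z <- matrix(stats::rnorm(n_starts * m), n_starts, m)
      z / sqrt(rowSums(z^2))
    })
    cand[cand[, 1] < 0, ] <- -cand[cand[, 1] < 0, , drop = FALSE]
    losses <- apply(cand, 1, function(a) profile_loss(a[-1], ctx))
    phi <- cand[which.min(losses), -1]
  }
  list(phi = phi, alpha = alpha_from_phi(phi), loss = min(losses))
}

#' Trust-region refinement of the index direction
#'
#' Minimizes the profile loss over the ball ||phi|| <= 1 - 1e-8 with the
#' PORT adaptive trust-region routine ([stats::nlminb()]) under box
#' bounds; the ball constraint is enforced through the loss penalty. The
#' result never has larger loss than the starting point.
#'
#' @param ctx profiling context.
#' @param phi0 starting value.
#' @return List with `phi`, `alpha`, `loss`, `converged`.
#' @export
optimize_index <- function(ctx, phi0) {
  b <- 1 - 1e-8
  phi0 <- pmin(pmax(phi0, -b), b)
  loss0 <- profile_loss(phi0, ctx)
  opt <- tryCatch(
    stats::nlminb(phi0, profile_loss, ctx = ctx,
                  lower = rep(-b, length(phi0)), upper = rep(b, length(phi0))),
    error = function(e) NULL)
  if (is.null(opt) || opt$objective > loss0 + 1e-12)
    return(list(phi = phi0, alpha = alpha_from_phi(phi0), loss = loss0,
                converged = is.null(opt)))
  list(phi = opt$par, alpha = alpha_from_phi(opt$par), loss = opt$objective,
       converged = opt$convergence == 0)
}

#' Fit the single-index varying-coefficient spatial lag model
#'
#' Estimates y_i = g(u_i'alpha) sum_j w_ij y_j + x_i'beta + eps_i with
#' unknown smooth g, unit-norm alpha (alpha_1 >= 0 for identification).
#' g is approximated by an order-p truncated power spline on
#' every-`knot_step`-th order statistic knots of t = u'alpha. The index
#' direction is profiled: for each candidate alpha the spline and
#' regression coefficients are concentrated out by joint least squares,
#' and alpha is updated by a grid-initialized trust-region minimization
#' of the residual sum of squares, with knots rebuilt from the current
#' index until the direction stabilizes. At the selected direction the
#' final coefficients (delta, beta) are re-estimated by two-stage least
#' squares: the spatial lag WY is endogenous, so its interaction block
#' with the spline basis is instrumented via the projection of WY onto
#' \[X, WX, W^2X, WU, W^2U\] (see [second_stage_iv()]), which removes the
#' simultaneity bias that plain least squares leaves in the coefficient
#' and residual-variance estimates.
#'
#' @param data a data frame with the response, covariate and index
#'   columns, or a `sisar_data` object from [simulate_sisar()] (in which
#'   case `weights` defaults to the simulated matrix).
#' @param weights a [spatial_weights] object (or plain matrix) whose row
#'   and column order matches the rows of `data`.
#' @param y_col response column name (default `"y"`).
#' @param x_cols covariate column names; default: all columns matching
#'   `^x[0-9]+$`.
#' @param u_cols index-variable column names; default: all columns
#'   matching `^u[0-9]+$`.
#' @param order spline order p (default 3).
#' @param knot_step order-statistic spacing for knot placement (default 10).
#' @param tol outer convergence tolerance on the sup-norm change of alpha.
#' @param max_outer maximum outer iterations.
#' @param grid_J grid resolution of the initial search (m = 2).
#' @param n_starts,seed random multistart settings for m > 2.
#' @return An object of class `sisar_fit` with elements `alpha`, `phi`,
#'   `beta`, `delta`, `basis`, `g_hat`, `fitted`, `wy_hat`, `sigma2`,
#'   `loss`, `iterations`, `converged`, `instruments`, plus bookkeeping.
#'   `tidy()`, `glance()`, `predict()` and `autoplot()` methods are
#'   available.
#' @export
sisar <- function(data, weights = NULL, y_col = "y", x_cols = NULL,
                  u_cols = NULL, order = 3L, knot_step = 10L, tol = 1e-4,
                  max_outer = 50L, grid_J = 40L, n_starts = 20L, seed = 1L) {
  if (inherits(data, "sisar_data")) {
    if (is.null(weights)) weights <- data$W
    data <- data$data
  }
  if (is.null(weights)) stop("a spatial weight matrix is required")
  df <- as.data.frame(data)
  if (is.null(x_cols)) x_cols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (is.null(u_cols)) u_cols <- grep("^u[0-9]+$", names(df), value = TRUE)
  miss <- setdiff(c(y_col, x_cols, u_cols), names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  Y <- as.numeric(df[[y_col]])
  X <- as.matrix(df[x_cols]); U <- as.matrix(df[u_cols])
  n <- length(Y)
  if (!inherits(weights, "spatial_weights")) weights <- spatial_weights(weights)
  if (weights$n != n) stop("weight matrix size does not match the data")
  ctx <- profile_context(Y, X, U, weights, order = order, knot_step = knot_step)
  if (n <= ncol(X) + ctx$order + 1L + floor(n / knot_step))
    warning("few observations relative to the number of coefficients")

  init <- initial_alpha(ctx, grid_J = grid_J, n_starts = n_starts, seed = seed)
  phi <- init$phi
  alpha <- init$alpha
  loss_path <- init$loss
  converged <- FALSE
  iter <- 0L
  while (iter < max_outer) {
    iter <- iter + 1L
    step <- optimize_index(ctx, phi)
    loss_path <- c(loss_path, step$loss)
    delta_alpha <- max(abs(step$alpha - alpha))
    phi <- step$phi; alpha <- step$alpha
    if (delta_alpha < tol) { converged <- TRUE; break }
  }

  ls_final <- stage_at_alpha(alpha, ctx, mode = "ls")
  st <- stage_at_alpha(alpha, ctx, mode = "iv")
  if (is.null(st)) stop("final coefficient stage failed at the converged index direction")
  g_hat <- drop(st$B %*% st$delta)
  fitted <- st$fitted                       # g_hat * (W y) + X beta
  sigma2 <- mean((Y - fitted)^2)
  if (diff(range(g_hat)) < 0.01)
    warning("fitted g is nearly constant; the index direction is weakly identified")
  structure(
    list(alpha = alpha, phi = phi, beta = stats::setNames(st$beta, x_cols),
         delta = st$delta, basis = st$basis, index = st$t, g_hat = g_hat,
         fitted = fitted, wy = ctx$wy, wy_hat = ctx$wy_hat, sigma2 = sigma2,
         loss = if (is.null(ls_final)) st$rss else ls_final$rss,
         loss_path = loss_path, iterations = iter,
         converged = converged, instruments = ctx$instruments,
         n = n, y = Y, y_col = y_col, x_cols = x_cols, u_cols = u_cols,
         options = list(order = order, knot_step = knot_step, tol = tol,
                        max_outer = max_outer, grid_J = grid_J)),
    class = "sisar_fit"
  )
}

#' @export
print.sisar_fit <- function(x, ...) {
  cat("Single-index varying-coefficient spatial lag model\n")
  cat(sprintf("  n = %d, %s after %d outer iteration(s)\n", x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  alpha:", paste(sprintf("%.4f", x$alpha), collapse = ", "), "\n")
  cat("  beta: ", paste(sprintf("%s = %.4f", names(x$beta), x$beta),
                        collapse = ", "), "\n")
  cat(sprintf("  sigma^2 = %.4f, fitted g range [%.3f, %.3f]\n",
              x$sigma2, min(x$g_hat), max(x$g_hat)))
  invisible(x)
}

#' In-sample fitted values of a varying-coefficient spatial lag fit
#'
#' Returns diag(g_hat) W Y + X beta_hat, the model's fitted values built
#' from the observed spatial lag; the mean squared residual equals the
#' fit's `sigma2` exactly. The spatial lag is a function of the observed
#' responses, so prediction is defined in-sample only.
#'
#' @param object a `sisar_fit`.
#' @param ... unused.
#' @return Numeric vector of fitted values.
#' @export
predict.sisar_fit <- function(object, ...) object$fitted

#' @export
residuals.sisar_fit <- function(object, ...) object$y - object$fitted

#' @export
fitted.sisar_fit <- function(object, ...) object$fitted
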