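test_that("instrument construction drops degenerate columns", {
  set.seed(1)
  n <- 36
  X <- matrix(rnorm(2 * n), n, 2)
  U <- matrix(rnorm(2 * n), n, 2)
  W0 <- spatial_weights(matrix(0, n, n))
  inst <- build_instruments(X, W0, U)
  expect_equal(inst$Q, X, ignore_attr = TRUE)
  expect_equal(inst$kept, c("x1", "x2"))
  # duplicated covariate column is dropped once
  instd <- build_instruments(cbind(X, X[, 1]), rook_grid(6), U)
  expect_false("x3" %in% instd$kept)
  # the main study design keeps the full 10-column block
  sim <- simulate_sisar(study_design(), seed = 1)
  inst10 <- build_instruments(as.matrix(sim$data[c("x1", "x2")]), sim$W,
                              as.matrix(sim$data[c("u1", "u2")]))
  expect_equal(length(inst10$kept), 10)
})

test_that("the first stage is an orthogonal projection", {
  set.seed(2)
  n <- 49
  W <- rook_grid(7)
  Q <- matrix(rnorm(4 * n), n, 4)
  Y <- rnorm(n)
  wy_hat <- first_stage(Q, W, Y)
  # projecting again changes nothing
  qrQ <- qr(Q)
  expect_lt(max(abs(qr.fitted(qrQ, wy_hat) - wy_hat)), 1e-10)
  # matches the brute-force normal equations
  WY <- drop(W$weights %*% Y)
  oracle <- drop(Q %*% solve(crossprod(Q), crossprod(Q, WY)))
  expect_lt(max(abs(wy_hat - oracle)), 1e-8)
  # a lag already in the span is reproduced exactly
  Yspan <- rnorm(n)
  Qspan <- cbind(drop(W$weights %*% Yspan), matrix(rnorm(2 * n), n, 2))
  expect_lt(max(abs(first_stage(Qspan, W, Yspan) - Qspan[, 1])), 1e-10)
})

test_that("the joint second stage equals the alternating fixed point", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 60
    t <- runif(n, -1, 1)
    b <- spline_basis(c(-0.3, 0.4), order = 2)
    B <- basis_matrix(t, b)
    X <- matrix(rnorm(2 * n), n, 2)
    lag <- rnorm(n, sd = 1) + 1    # keep diag(lag) B well conditioned
    Y <- rnorm(n)
    st <- second_stage(Y, X, B, lag)
    alt <- alternating_stage(Y, X, B, lag)
    expect_lt(max(abs(st$delta - alt$delta)), 1e-8)
    expect_lt(max(abs(st$beta - alt$beta)), 1e-8)
  }
})

test_that("the second stage recovers exact coefficients on noise-free data", {
  set.seed(4)
  n <- 80
  t <- runif(n, -1, 1)
  b <- spline_basis(c(-0.2, 0.5), order = 3)
  B <- basis_matrix(t, b)
  X <- matrix(rnorm(2 * n), n, 2)
  delta <- rnorm(b$dimension, sd = 0.3)
  beta <- c(1, -2)
  lag <- rnorm(n) + 2
  Y <- lag * drop(B %*% delta) + drop(X %*% beta)
  st <- second_stage(Y, X, B, lag)
  expect_lt(max(abs(st$delta - delta)), 1e-8)
  expect_lt(max(abs(st$beta - beta)), 1e-8)
  # the instrumented stage leaves an exact solution untouched
  iv <- second_stage_iv(Y, X, B, lag, lag + rnorm(n, sd = 0.2))
  expect_lt(max(abs(iv$delta - delta)), 1e-8)
  expect_lt(max(abs(iv$beta - beta)), 1e-8)
})

test_that("a zero lag vector makes the spline block unidentifiable", {
  set.seed(5)
  n <- 50
  B <- basis_matrix(runif(n), spline_basis(0.5, 2))
  X <- matrix(rnorm(n), n, 1)
  expect_error(second_stage(rnorm(n), X, B, rep(0, n)), "zero column")
})

test_that("the profile loss is nonnegative, near zero at the truth on clean data", {
  rs <- representable_sim()
  ctx <- sisar:::profile_context(rs$Y, rs$X, rs$U, rs$W)
  phi_true <- rs$alpha[2]
  expect_gte(profile_loss(0.3, ctx), 0)
  expect_lt(profile_loss(phi_true, ctx), 1e-10)
  for (pert in c(-0.3, -0.1, 0.1)) {
    expect_lt(profile_loss(phi_true, ctx), profile_loss(phi_true + pert, ctx))
  }
  expect_gt(profile_loss(c(1.5), ctx), 1e10)  # outside the unit ball
})

test_that("grid initialization lands near the true index direction", {
  d <- study_design(sigma2 = 1e-12)  # effectively noise free
  sim <- simulate_sisar(d, seed = 6)
  ctx <- sisar:::profile_context(sim$data$y,
                                 as.matrix(sim$data[c("x1", "x2")]),
                                 as.matrix(sim$data[c("u1", "u2")]), sim$W)
  init <- initial_alpha(ctx, grid_J = 40)
  expect_lt(max(abs(init$alpha - c(0.5, sqrt(3) / 2))), 0.05)
})

test_that("the trust-region refinement never increases the loss", {
  sim <- simulate_sisar(study_design(h = 8), seed = 7)
  ctx <- sisar:::profile_context(sim$data$y,
                                 as.matrix(sim$data[c("x1", "x2")]),
                                 as.matrix(sim$data[c("u1", "u2")]), sim$W)
  for (start in c(-0.8, 0.1, 0.87)) {
    res <- optimize_index(ctx, start)
    expect_lte(res$loss, profile_loss(start, ctx) + 1e-12)
    expect_lte(sum(res$phi^2), 1)
  }
  # agreement with a fine brute-force grid
  phis <- seq(-0.999, 0.999, by = 1e-3)
  L <- vapply(phis, function(p) profile_loss(p, ctx), numeric(1))
  best <- optimize_index(ctx, phis[which.min(L)])
  expect_lt(abs(best$phi - phis[which.min(L)]), 2e-3)
})

test_that("the full fit recovers a representable model exactly", {
  rs <- representable_sim()
  f <- sisar(rs$data, rs$W)
  expect_true(f$converged)
  expect_lt(max(abs(f$alpha - rs$alpha)), 1e-4)
  expect_lt(max(abs(unname(f$beta) - rs$beta)), 1e-4)
  expect_lt(max(abs(fitted(f) - rs$Y)), 1e-6)
  expect_lt(f$sigma2, 1e-12)
})

test_that("fits are identified with unit-norm alpha and alpha1 >= 0", {
  sim <- simulate_sisar(study_design(h = 8), seed = 8)
  f <- sisar(sim)
  expect_equal(sum(f$alpha^2), 1, tolerance = 1e-12)
  expect_gte(f$alpha[1], 0)
  expect_equal(mean((f$y - fitted(f))^2), f$sigma2, tolerance = 1e-12)
  expect_true(all(diff(f$loss_path) <= 1e-8))  # outer loop never ascends
})

test_that("sign-flipped truth yields the same identified representative", {
  # g2(t) = g(-t) with alpha2 = -alpha generates identical data; the fit
  # must return the alpha1 >= 0 representative and the same fitted g
  h <- 8
  W <- rook_grid(h)
  set.seed(9)
  n <- h^2
  U <- matrix(runif(2 * n, -1, 1), n, 2)
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  alpha <- c(0.6, 0.8)
  g <- function(t) 0.4 * sin(2 * t)
  Y <- solve(diag(n) - g(drop(U %*% alpha)) * W$weights,
             drop(X %*% c(1, 2)) + rnorm(n, sd = 0.1))
  dat <- tibble::tibble(y = Y, x1 = X[, 1], x2 = X[, 2], u1 = U[, 1], u2 = U[, 2])
  f <- sisar(dat, W)
  expect_gte(f$alpha[1], 0)
  expect_lt(max(abs(f$alpha - alpha)), 0.05)
  expect_lt(mean((f$g_hat - g(drop(U %*% alpha)))^2), 0.01)
})

test_that("the instrumented stage reduces the systematic bias of g", {
  # oracle decomposition at the true index direction: the IV correction
  # targets the simultaneity bias of the least-squares spline stage.
  # Compared on the interior of the index range (spline tails are
  # variance-dominated) with the Monte Carlo variance contribution
  # removed from the squared-bias estimate.
  alpha <- c(0.5, sqrt(3) / 2)
  nrep <- 100
  t0 <- drop(grid_coordinates(15) %*% alpha)
  gt <- sin(t0)
  interior <- t0 >= quantile(t0, 0.1) & t0 <= quantile(t0, 0.9)
  G_ls <- matrix(NA_real_, nrep, 225)
  G_iv <- matrix(NA_real_, nrep, 225)
  for (s in seq_len(nrep)) {
    sim <- simulate_sisar(study_design(), seed = 1200 + s)
    Y <- sim$data$y
    X <- as.matrix(sim$data[c("x1", "x2")])
    U <- as.matrix(sim$data[c("u1", "u2")])
    ctx <- sisar:::profile_context(Y, X, U, sim$W)
    t <- drop(U %*% alpha)
    B <- basis_matrix(t, spline_basis(select_knots(t, 10), 3))
    G_ls[s, ] <- drop(B %*% second_stage(Y, X, B, ctx$wy)$delta)
    G_iv[s, ] <- drop(B %*% second_stage_iv(Y, X, B, ctx$wy, ctx$wy_hat)$delta)
  }
  bias2 <- function(M) {
    M <- M[, interior]
    mean((colMeans(M) - gt[interior])^2) - mean(apply(M, 2, var)) / nrep
  }
  expect_lt(bias2(G_iv), bias2(G_ls))
})

test_that("estimation error shrinks monotonically with the noise level", {
  mse_a1 <- sapply(c(1, 0.25, 0.01), function(s2) {
    est <- sapply(1:25, function(s) {
      sisar(simulate_sisar(study_design(h = 10, sigma2 = s2), seed = 90 + s))$alpha[1]
    })
    mean((est - 0.5)^2)
  })
  expect_true(all(diff(mse_a1) < 0))
})

test_that("fit input validation names the offending column", {
  sim <- simulate_sisar(study_design(h = 6), seed = 1)
  expect_error(sisar(sim$data, sim$W, x_cols = c("x1", "x9")), "x9")
  expect_error(sisar(sim$data[1:10, ], sim$W), "does not match")
  expect_error(sisar(sim$data), "required")
})

test_that("the residual bootstrap yields plausible dispersion", {
  sim <- simulate_sisar(study_design(h = 8, sigma2 = 0.25), seed = 31)
  f <- sisar(sim)
  bt <- sisar_bootstrap(f, sim, nboot = 30, seed = 32)
  expect_equal(bt$term, c("alpha1", "alpha2", "x1", "x2"))
  expect_true(all(bt$se_boot > 0))
  expect_true(all(bt$se_boot < 1))
  expect_identical(bt, sisar_bootstrap(f, sim, nboot = 30, seed = 32))
})
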