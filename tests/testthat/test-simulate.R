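test_that("grid coordinates follow the half-unit row-major layout", {
  U <- grid_coordinates(15)
  expect_equal(U[1, ], c(0, 0))
  expect_equal(U[15, ], c(7, 0))
  expect_equal(U[16, ], c(0, 0.5))
  expect_equal(nrow(U), 225)
})

test_that("disk coordinates are area-uniform and seeded", {
  U <- disk_coordinates(1e5, R = 1, seed = 11)
  expect_true(all(rowSums(U^2) <= 1 + 1e-12))
  expect_identical(U, disk_coordinates(1e5, R = 1, seed = 11))
  expect_lt(abs(mean(U[, 1])), 0.01)
  expect_lt(abs(mean(U[, 2])), 0.01)
  expect_lt(abs(mean(rowSums(U^2)) - 0.5), 0.01)  # E r^2 = R^2/2
})

test_that("covariate laws have the right moments and supports", {
  x <- draw_covariates(1e5, 1, "unif", seed = 1)
  expect_lt(abs(mean(x)), 0.01)
  expect_true(all(x >= -1 & x <= 1))
  x01 <- draw_covariates(1e5, 1, "unif01", seed = 1)
  expect_lt(abs(mean(x01) - 0.5), 0.01)
  expect_lt(abs(mean(draw_covariates(1e5, 1, "chisq2", seed = 2)) - 2), 0.05)
  xb <- draw_covariates(1e4, 2, "beta22", seed = 3)
  expect_true(all(xb >= 0 & xb <= 1))
  expect_error(draw_covariates(10, 1, "cauchy"), "arg")
})

test_that("the sine coefficient field is bounded and validated", {
  U <- grid_coordinates(5)
  expect_equal(sine_rho_field(U, amplitude = 0), rep(0, 25))
  r <- sine_rho_field(U, amplitude = 0.8, frequency = 1)
  expect_true(all(abs(r) < 0.8 + 1e-15))
  expect_equal(r, 0.8 * sin(U[, 1] + U[, 2]))
  expect_error(sine_rho_field(U, amplitude = 1), "stable")
})

test_that("the reduced form is solved exactly", {
  d <- sim_design(h = 8)
  sim <- simulate_sisar(d, seed = 5)
  n <- d$n
  A <- diag(n) - sim$data$g_true * sim$W$weights
  lhs <- drop(A %*% sim$data$y)
  rhs <- drop(as.matrix(sim$data[c("x1", "x2")]) %*% d$beta) + sim$data$eps
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("degenerate designs reduce to plain regression", {
  d0 <- sim_design(h = 6, g = function(t) rep(0, length(t)))
  sim <- simulate_sisar(d0, seed = 2)
  xb <- drop(as.matrix(sim$data[c("x1", "x2")]) %*% d0$beta)
  expect_equal(sim$data$y, xb + sim$data$eps, tolerance = 1e-12)
  dz <- sim_design(h = 6, weights = spatial_weights(matrix(0, 36, 36)))
  simz <- simulate_sisar(dz, seed = 2)
  xbz <- drop(as.matrix(simz$data[c("x1", "x2")]) %*% dz$beta)
  expect_equal(simz$data$y, xbz + simz$data$eps, tolerance = 1e-12)
})

test_that("simulation is a pure function of design and seed", {
  d <- sim_design(h = 7)
  expect_identical(simulate_sisar(d, seed = 3)$data, simulate_sisar(d, seed = 3)$data)
  dd <- sim_design(region = "disk", n = 50)
  a <- simulate_sisar(dd, seed = 4); b <- simulate_sisar(dd, seed = 4)
  expect_identical(a$data, b$data)
  expect_identical(a$W$weights, b$W$weights)
  expect_false(identical(simulate_sisar(d, seed = 3)$data,
                         simulate_sisar(d, seed = 4)$data))
})

test_that("unstable coefficient fields are rejected", {
  d <- sim_design(h = 6, g = function(t) rep(1.2, length(t)))
  expect_error(simulate_sisar(d, seed = 1), "unstable")
})

test_that("sine-field data mislead the homogeneous SAR fit upward in rho", {
  # heterogeneous dependence with zero mean field: a homogeneous fit lands
  # on a compromise rho and a distorted variance (direction, not magnitude)
  d <- sim_design(covariate_law = "unif01")
  rho <- sine_rho_field(grid_coordinates(15), 0.8, 1)
  s2 <- mean(sapply(1:20, function(s) {
    fit_sar(simulate_sisar(d, seed = 50 + s, rho = rho))$sigma2
  }))
  expect_gt(s2, 1.5)
})
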