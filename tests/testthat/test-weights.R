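test_that("rook contiguity matches hand enumeration", {
  expect_equal(rook_grid(1)$weights, matrix(0, 1, 1))
  w2 <- rook_grid(2, standardize = FALSE)$weights
  expect_equal(rowSums(w2 > 0), rep(2, 4), ignore_attr = TRUE)
  w2s <- rook_grid(2)$weights
  expect_equal(sort(unique(w2s[w2s > 0])), 0.5)
  expect_equal(rook_grid(15)$n, 225)
  # interior unit of a 3x3 grid touches all four edge-sharing cells
  w3 <- rook_grid(3, standardize = FALSE)$weights
  expect_equal(which(w3[5, ] == 1), c(2, 4, 6, 8))
})

test_that("bishop contiguity links corners only", {
  expect_equal(bishop_grid(1)$weights, matrix(0, 1, 1))
  w2 <- bishop_grid(2)$weights
  expect_equal(rowSums(w2 > 0), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unique(w2[w2 > 0]), 1)
  w3 <- bishop_grid(3, standardize = FALSE)$weights
  expect_equal(which(w3[1, ] == 1), 5)  # corner cell sees only the centre
})

test_that("rook and bishop supports are disjoint", {
  for (h in 2:6) {
    r <- rook_grid(h, standardize = FALSE)$weights
    b <- bishop_grid(h, standardize = FALSE)$weights
    expect_equal(sum(r * b), 0)
  }
})

test_that("group-interaction matrix is block row-stochastic", {
  expect_equal(case_groups(1, 2)$weights, matrix(c(0, 1, 1, 0), 2, 2))
  w <- case_groups(3, 75)
  expect_equal(w$n, 225)
  expect_equal(rowSums(w$weights), rep(1, 225), ignore_attr = TRUE)
  expect_equal(sum(w$weights[1:75, 76:225]), 0)  # no cross-group links
  expect_error(case_groups(2, 1), "group size")
})

test_that("k-nearest-neighbour weights follow the distance ranking", {
  pts <- rbind(c(0, 0), c(1, 0), c(3, 0))
  w <- knn_points(pts, 1)$weights
  expect_equal(which(w[1, ] > 0), 2)
  expect_equal(which(w[3, ] > 0), 2)
  expect_false(isSymmetric(w))
  # k = n-1 links everything uniformly
  set.seed(1)
  p5 <- matrix(rnorm(10), 5, 2)
  w5 <- knn_points(p5, 4)$weights
  expect_equal(w5[row(w5) != col(w5)], rep(0.25, 20))
  expect_error(knn_points(pts, 0), "positive")
  expect_error(knn_points(pts, 3), "smaller")
  # exactly k nonzeros per row on tie-free point sets
  set.seed(2)
  p <- matrix(rnorm(40), 20, 2)
  for (k in c(1, 3, 6)) {
    expect_equal(rowSums(knn_points(p, k)$weights > 0), rep(k, 20),
                 ignore_attr = TRUE)
  }
})

test_that("inverse-distance weights are distance-symmetric before rows differ", {
  w2 <- inverse_distance(rbind(c(0, 0), c(0, 7)))$weights
  expect_equal(w2, matrix(c(0, 1, 1, 0), 2, 2))
  w3 <- inverse_distance(rbind(c(0, 0), c(1, 0), c(2, 0)))$weights
  expect_equal(w3[2, ], c(0.5, 0, 0.5))
  expect_error(inverse_distance(rbind(c(0, 0), c(0, 0), c(1, 1))), "oincident")
})

test_that("random weights are seeded and standardize to unit or empty rows", {
  w1 <- random_weights(20, density = 1)$weights
  expect_equal(w1[row(w1) != col(w1)], rep(1 / 19, 380))
  a <- random_weights(30, density = 0.1, seed = 9)
  b <- random_weights(30, density = 0.1, seed = 9)
  expect_identical(a$weights, b$weights)
  suppressMessages({
    w <- random_weights(225, density = 0.02, seed = 1)$weights
  })
  expect_true(all(abs(rowSums(w) - 1) < 1e-12 | rowSums(w) == 0))
})

test_that("row_normalize divides rows by their sums and is idempotent", {
  m <- matrix(c(0, 2, 3, 0), 2, 2, byrow = TRUE)
  w <- row_normalize(m)
  expect_equal(w$weights, matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(row_normalize(w)$weights, w$weights)
  expect_equal(row_normalize(matrix(0, 3, 3))$weights, matrix(0, 3, 3))
})

test_that("constructors keep the core invariants", {
  set.seed(4)
  mats <- list(rook_grid(4), bishop_grid(5), case_groups(2, 5),
               knn_points(matrix(rnorm(24), 12, 2), 3),
               inverse_distance(matrix(rnorm(16), 8, 2)),
               suppressMessages(random_weights(15, 0.3, seed = 2)))
  for (w in mats) {
    expect_equal(diag(w$weights), rep(0, w$n), ignore_attr = TRUE)
    expect_true(all(w$weights >= 0))
    rs <- rowSums(w$weights)
    expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
  }
  expect_error(spatial_weights(matrix(c(1, 0, 0, 0), 2, 2)), "diagonal")
  expect_error(spatial_weights(matrix(c(0, -1, 0, 0), 2, 2)), "nonnegative")
})

test_that("weight_total sums all entries", {
  expect_equal(weight_total(rook_grid(3, standardize = FALSE)), 24)
  expect_equal(weight_total(rook_grid(3)), 9)
})
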