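test_that("pointwise distance matrix is the per-pair Euclidean norm", {
  D <- dtw_distance_matrix(c(1, 2), c(1, 3))
  expect_equal(D, rbind(c(0, 2), c(1, 1)))

  x <- matrix(rnorm(3 * 7), nrow = 3)
  expect_equal(diag(dtw_distance_matrix(x, x)), rep(0, 7))

  a <- matrix(c(0, 0), ncol = 1)
  b <- matrix(c(3, 4), ncol = 1)
  expect_equal(dtw_distance_matrix(a, b)[1, 1], 5)

  expect_error(dtw_distance_matrix(matrix(0, 2, 3), matrix(0, 3, 3)),
               "channel counts")
})

test_that("cumulative matrix satisfies the DP boundary and recurrence", {
  C <- dtw_cumulative(rbind(c(1, 1), c(1, 1)))
  expect_equal(C, rbind(c(1, 2), c(2, 2)))

  Z <- dtw_cumulative(matrix(0, 4, 5))
  expect_true(all(Z == 0))

  d <- matrix(c(2, 1, 3, 5), nrow = 1)
  expect_equal(as.numeric(dtw_cumulative(d)), cumsum(c(2, 1, 3, 5)))
})

test_that("backtracking returns valid, deterministic warping paths", {
  x <- sin(1:10)
  C <- dtw_cumulative(dtw_distance_matrix(x, x))
  path <- dtw_backtrack(C)
  expect_equal(path, cbind(1:10, 1:10))   # zero-cost diagonal

  C1 <- dtw_cumulative(matrix(c(1, 2, 3, 4), nrow = 1))
  expect_equal(dtw_backtrack(C1), cbind(rep(1, 4), 1:4))  # forced moves

  # all-ties cumulative matrix: diagonal preferred
  Ct <- matrix(0, 3, 3)
  expect_equal(dtw_backtrack(Ct), cbind(1:3, 1:3))

  # path invariants on a random pair
  set.seed(1)
  C2 <- dtw_cumulative(dtw_distance_matrix(rnorm(8), rnorm(6)))
  p <- dtw_backtrack(C2)
  expect_equal(p[1, ], c(1, 1))
  expect_equal(p[nrow(p), ], c(8, 6))
  steps <- diff(p)
  expect_true(all(steps >= 0 & steps <= 1))
  expect_true(all(rowSums(steps) >= 1))
})

test_that("hand-derived alignment costs are reproduced", {
  expect_equal(mdtw_distance(c(1, 2, 3), c(2, 2, 2, 3, 3)), 1)
  r <- mdtw_distance(c(1, 2, 3), c(2, 2, 2, 3, 3), keep_matrices = TRUE)
  expect_equal(r$distance, 1)
  expect_equal(r$distance,
               sum(abs(c(1, 2, 3)[r$path[, 1]] -
                         c(2, 2, 2, 3, 3)[r$path[, 2]])))
})

test_that("single-channel input reduces both strategies to scalar DTW", {
  set.seed(2)
  for (k in 1:20) {
    x <- rnorm(sample(3:10, 1))
    y <- rnorm(sample(3:10, 1))
    C <- dtw_cumulative(dtw_distance_matrix(x, y))
    scalar <- C[length(x), length(y)]
    expect_equal(mdtw_distance(x, y, strategy = "dependent"), scalar,
                 tolerance = 1e-12)
    expect_equal(mdtw_distance(x, y, strategy = "independent"), scalar,
                 tolerance = 1e-12)
  }
})

test_that("distance is symmetric and zero only for identical alignments", {
  set.seed(3)
  for (k in 1:50) {
    x <- matrix(rnorm(2 * sample(3:12, 1)), nrow = 2)
    y <- matrix(rnorm(2 * sample(3:12, 1)), nrow = 2)
    expect_equal(mdtw_distance(x, y), mdtw_distance(y, x),
                 tolerance = 1e-12)
    expect_equal(mdtw_distance(x, x), 0)
  }
  # zero distance implies every aligned pair is equal
  x <- c(1, 2, 2, 3)
  y <- c(1, 2, 3, 3)
  r <- mdtw_distance(x, y, keep_matrices = TRUE)
  expect_equal(r$distance, 0)
  expect_true(all(x[r$path[, 1]] == y[r$path[, 2]]))
})

test_that("dependent distance is invariant to channel permutation", {
  set.seed(4)
  x <- matrix(rnorm(4 * 9), nrow = 4)
  y <- matrix(rnorm(4 * 11), nrow = 4)
  for (k in 1:5) {
    perm <- sample(4)
    expect_equal(mdtw_distance(x[perm, ], y[perm, ]),
                 mdtw_distance(x, y), tolerance = 1e-12)
  }
})

test_that("appending a sample pair adds at least its pointwise cost", {
  # the optimal path must end by aligning the appended samples, so the
  # total cost is bounded below by their pointwise distance
  set.seed(5)
  for (k in 1:30) {
    x <- rnorm(sample(2:8, 1))
    y <- rnorm(sample(2:8, 1))
    a <- rnorm(1)
    b <- a + runif(1, 0.1, 2)
    expect_gte(mdtw_distance(c(x, a), c(y, b)), abs(a - b))
  }
})

test_that("DP distance equals exhaustive path enumeration on small pairs", {
  seqs <- all_sequences(3)
  for (x in seqs) {
    for (y in seqs) {
      expect_equal(mdtw_distance(x, y), dtw_oracle(x, y))
    }
  }
})

test_that("the optional warping window reproduces the unconstrained
           distance when wide enough", {
  set.seed(6)
  x <- rnorm(30)
  y <- rnorm(28)
  expect_equal(mdtw_distance(x, y, window = 30), mdtw_distance(x, y))
  expect_gte(mdtw_distance(x, y, window = 2), mdtw_distance(x, y))
})
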