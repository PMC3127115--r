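test_that("predictions follow the closed form and its limit laws", {
  x <- matrix(c(0, 1, 2))
  y <- c(0, 1, 0)
  # hand-evaluated kernel average at the middle pattern, delta = 1
  m <- grnn(x, y, delta = 1, scale = "none")
  expect_equal(predict(m, matrix(1)),
               (exp(-0.5) * 0 + 1 + exp(-0.5) * 0) / (2 * exp(-0.5) + 1))
  # delta -> 0: memorization at stored patterns
  m0 <- grnn(x, y, delta = 1e-6, scale = "none")
  expect_equal(predict(m0, x), y)
  # delta -> Inf: global mean everywhere
  minf <- grnn(x, y, delta = 1e6, scale = "none")
  expect_equal(predict(minf, matrix(c(-5, 0.3, 7))), rep(mean(y), 3),
               tolerance = 1e-6)
  # symmetric patterns at equal distance average their targets
  msym <- grnn(matrix(c(-2, 2)), c(0, 1), delta = 0.7, scale = "none")
  expect_equal(predict(msym, matrix(0)), 0.5)
  # single pattern predicts its target everywhere
  m1 <- grnn(matrix(5), 3.2, delta = 0.1)
  expect_equal(predict(m1, matrix(c(-100, 5, 100))), rep(3.2, 3))
})

test_that("far queries at tiny delta fall back to the nearest pattern", {
  m <- grnn(matrix(c(0, 10)), c(1, 2), delta = 1e-8, scale = "none")
  expect_equal(predict(m, matrix(c(3, 7))), c(1, 2))
  # tie broken toward the lowest pattern index
  mt <- grnn(matrix(c(-1, 1)), c(5, 9), delta = 1e-8, scale = "none")
  expect_equal(predict(mt, matrix(0)), 5)
})

test_that("predictions are convex combinations and permutation invariant", {
  set.seed(31)
  for (rep in 1:5) {
    x <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
    q <- matrix(rnorm(20), 5, 4)
    m <- grnn(x, y, delta = runif(1, 0.3, 2), scale = "none")
    p <- predict(m, q)
    expect_true(all(p >= min(y) - 1e-12 & p <= max(y) + 1e-12))
    perm <- sample(10)
    mp <- grnn(x[perm, ], y[perm], delta = m$delta, scale = "none")
    expect_equal(predict(mp, q), p, tolerance = 1e-12)
  }
})

test_that("predictions match the naive double-loop oracle", {
  set.seed(32)
  for (rep in 1:5) {
    x <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    q <- rnorm(3)
    m <- grnn(x, y, delta = 0.8, scale = "none")
    expect_equal(predict(m, matrix(q, 1)), oracle_grnn(x, y, q, 0.8),
                 tolerance = 1e-12)
  }
})

test_that("input scaling is fitted on patterns and reused at prediction", {
  set.seed(33)
  x <- cbind(rnorm(20, 0, 1), rnorm(20, 100, 50))
  y <- rnorm(20)
  q <- cbind(rnorm(4), rnorm(4, 100, 50))
  m <- grnn(x, y, delta = 0.5, scale = "zscore")
  # manual scaling reproduces the same predictions
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  qs <- sweep(sweep(q, 2, ctr), 2, scl, "/")
  mraw <- grnn(xs, y, delta = 0.5, scale = "none")
  expect_equal(predict(m, q), predict(mraw, qs), tolerance = 1e-12)
  # constant column gets unit scale instead of erroring
  xc <- cbind(x[, 1], 7)
  mc <- grnn(xc, y, delta = 0.5, scale = "zscore")
  expect_equal(mc$scaling$scale[2], 1)
  expect_error(grnn(x, y, delta = 0), "positive")
  expect_error(predict(m, q[, 1, drop = FALSE]), "columns")
})

test_that("smoothing-factor sweep minimizes the requested criterion", {
  single <- grnn_sweep(matrix(rnorm(10)), rnorm(10), grid = 0.3)
  expect_equal(single$best_delta, 0.3)
  # smooth noiseless target: LOO curve has an interior minimum and the
  # selected bandwidth recovers the function well
  sim <- simulate_descriptor_table(n = 200, n_relevant = 2, n_noise = 0,
                                   rho = 0, noise_sd = 0, seed = 41)
  truth <- sim_structure(sim)
  x <- as.matrix(sim[, truth$relevant])
  tr <- sim$split == "train"
  sw <- grnn_sweep(x[tr, ], sim$expt_bde[tr], criterion = "loo",
                   scale = "none")
  expect_equal(sw$values[which(sw$grid == sw$best_delta)], min(sw$values))
  expect_gt(sw$best_delta, min(sw$grid))
  expect_lt(sw$best_delta, max(sw$grid))
  m <- grnn(x[tr, ], sim$expt_bde[tr], delta = sw$best_delta, scale = "none")
  test_rmse <- rms(sim$expt_bde[!tr] - predict(m, x[!tr, ]))
  expect_lt(test_rmse, 0.1 * sd(sim$expt_bde))
  # held-out criterion requires a held-out set
  expect_error(grnn_sweep(x[tr, ], sim$expt_bde[tr], criterion = "test"),
               "newdata")
})
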