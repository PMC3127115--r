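test_that("column standardization gives mean 0, sample sd 1", {
  z <- standardize_columns(cbind(a = c(1, 2, 3)))
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  x <- matrix(rnorm(40, mean = 5, sd = 3), 10, 4)
  z <- standardize_columns(x)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4))
  # idempotence (up to the recorded center/scale attributes)
  expect_equal(unname(standardize_columns(z)), unname(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize_columns(cbind(a = 1:5, b = rep(2, 5))), "b")
})

test_that("correlation matrix has the defining properties", {
  z <- standardize_columns(cbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
  expect_equal(unname(correlation_matrix(z)), diag(2))  # orthogonal columns
  x <- cbind(a = c(1, 3, 7, 2), b = 2 * c(1, 3, 7, 2) + 5)
  r <- correlation_matrix(standardize_columns(x))
  expect_equal(unname(r), matrix(1, 2, 2))              # duplicated data
  set.seed(21)
  r <- correlation_matrix(standardize_columns(matrix(rnorm(50), 10, 5)))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
})

test_that("eigendecomposition is sorted, sign-fixed, and reconstructs R", {
  expect_equal(eigen_correlation(diag(3))$values, rep(1, 3))
  # closed form for a 2x2 correlation matrix
  rho <- 0.63
  e <- eigen_correlation(matrix(c(1, rho, rho, 1), 2))
  expect_equal(e$values, c(1 + rho, 1 - rho))
  set.seed(22)
  z <- standardize_columns(matrix(rnorm(60), 12, 5))
  r <- correlation_matrix(z)
  e <- eigen_correlation(r)
  expect_true(all(diff(e$values) <= 0))
  expect_equal(max(abs(r - e$vectors %*% diag(e$values) %*% t(e$vectors))),
               0, tolerance = 1e-8)
  # unit norm, largest-magnitude entry positive
  expect_equal(unname(colSums(e$vectors^2)), rep(1, 5))
  for (j in 1:5) expect_gt(e$vectors[which.max(abs(e$vectors[, j])), j], 0)
  expect_error(eigen_correlation(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("eigenpairs agree with a power-iteration oracle", {
  set.seed(23)
  for (rep in 1:5) {
    z <- standardize_columns(matrix(rnorm(100), 20, 5))
    r <- correlation_matrix(z)
    e <- eigen_correlation(r)
    o <- oracle_eigen(r)
    expect_equal(e$values, o$values, tolerance = 1e-6)
    for (j in 1:5) {
      # eigenvectors defined up to sign
      expect_equal(min(max(abs(e$vectors[, j] - o$vectors[, j])),
                       max(abs(e$vectors[, j] + o$vectors[, j]))),
                   0, tolerance = 1e-6)
    }
  }
})

test_that("component selection policies work", {
  expect_equal(select_components(c(3, 1, 0, 0), "fixed", 2), 2L)
  expect_error(select_components(c(3, 1, 0, 0), "fixed", 5), "1..4")
  expect_equal(select_components(rep(1, 4), "cumulative", 1), 4L)
  expect_equal(select_components(c(3, 1, 0, 0), "cumulative", 0.5), 1L)
  expect_error(select_components(c(3, 1), "cumulative", 1.2), "exceed")
})

test_that("scores have eigenvalue variances and are uncorrelated on the fit data", {
  set.seed(24)
  x <- matrix(rnorm(200), 40, 5) %*% matrix(runif(25), 5, 5)
  fit <- cor_pca(x)
  expect_equal(sum(fit$values), 5)            # trace of a correlation matrix
  expect_equal(sum(fit$weights), 1)
  scores <- predict(fit, x)
  expect_equal(unname(apply(scores, 2, var)), fit$values, tolerance = 1e-8)
  off <- cor(scores)[upper.tri(diag(5))]
  expect_true(all(abs(off) < 1e-7))
  # zero standardized row maps to the zero score vector
  z0 <- matrix(fit$center, 1)
  expect_equal(unname(predict(fit, z0))[1, ], rep(0, fit$ncomp),
               tolerance = 1e-12)
  expect_error(predict(fit, x[, 1:3]), "columns")
})

test_that("benchmark 8-descriptor PCA shows the known rank deficiency", {
  tab <- yno_bde()
  sel <- gra(tab)$selected
  fit <- cor_pca(tab[, sel], ncomp = 6)
  # dE is an exact linear combination of E_HOMO and E_LUMO (up to rounding)
  expect_lt(fit$values[8], 5e-3)
  expect_gt(fit$values[1], 3.5)
})
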