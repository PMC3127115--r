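test_that("series normalization modes behave as defined", {
  expect_equal(gra_normalize(c(1, 2, 3), "minmax"), c(0, 0.5, 1))
  expect_equal(gra_normalize(c(2, 4, 6), "mean"), c(0.5, 1, 1.5))
  x <- rnorm(10)
  expect_identical(gra_normalize(x, "none"), x)
  expect_error(gra_normalize(c(2, 2, 2), "minmax"), "constant")
  expect_error(gra_normalize(c(-1, 0, 1), "mean"), "zero mean")
})

test_that("relational coefficients follow the canonical closed form", {
  # contrast identical to reference: all coefficients 1 (Dmax = 0 case)
  x0 <- c(1, 2, 3, 4)
  expect_true(all(gra_coefficients(x0, cbind(x0), normalize = "none") == 1))
  # hand case: deviations all equal, Dmin = Dmax = 1 -> r = 1 everywhere
  expect_equal(
    unname(gra_coefficients(c(0, 1), cbind(c(1, 0)), rho = 0.5,
                            normalize = "none"))[, 1],
    c(1, 1))
  # two series so Dmin/Dmax are nondegenerate: evaluate by hand
  # deviations: series1 = (0, 1), series2 = (2, 0); Dmin = 0, Dmax = 2
  co <- gra_coefficients(c(0, 1), cbind(c(0, 0), c(-2, 1)), rho = 0.5,
                         normalize = "none")
  expect_equal(unname(co), cbind(c(1, 0.5), c(1 / 3, 1)))
})

test_that("coefficients match a brute-force double-loop oracle", {
  set.seed(11)
  for (rep in 1:5) {
    x0 <- rnorm(6)
    contrast <- matrix(rnorm(24), 6, 4)
    expect_equal(unname(gra_coefficients(x0, contrast, rho = 0.5,
                                         normalize = "none")),
                 oracle_gra_coefficients(x0, contrast, 0.5),
                 tolerance = 1e-12)
  }
})

test_that("coefficients are in (0,1], equal 1 only at the minimum deviation", {
  set.seed(12)
  for (rep in 1:10) {
    x0 <- rnorm(8)
    contrast <- matrix(rnorm(8 * 3), 8, 3)
    co <- gra_coefficients(x0, contrast, rho = 0.5, normalize = "none")
    expect_true(all(co > 0 & co <= 1))
    delta <- abs(matrix(x0, 8, 3) - contrast)
    expect_equal(unname(co == 1), unname(delta == min(delta)))
  }
})

test_that("coefficients are nondecreasing in the distinguishing coefficient", {
  set.seed(13)
  x0 <- rnorm(8)
  contrast <- matrix(rnorm(8 * 3), 8, 3)
  rhos <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cos <- lapply(rhos, function(r)
    gra_coefficients(x0, contrast, rho = r, normalize = "none"))
  for (i in seq_len(length(rhos) - 1L)) {
    expect_true(all(cos[[i + 1L]] - cos[[i]] >= -1e-12))
  }
})

test_that("min-max normalized coefficients are invariant to affine rescaling", {
  tab <- make_table(n = 10)
  base <- gra(tab, normalize = "minmax")
  tab$alpha_pol <- 3.7 * tab$alpha_pol - 120   # affine change of units
  tab$expt_bde <- 0.5 * tab$expt_bde + 4
  rescaled <- gra(tab, normalize = "minmax")
  expect_equal(rescaled$coefficients, base$coefficients, tolerance = 1e-10)
})

test_that("relation degrees are row means of the coefficients", {
  co <- cbind(a = c(1, 1, 1), b = c(0.5, 1, 0.75))
  expect_equal(relation_degree(co), c(a = 1, b = 0.75))
  expect_error(relation_degree(matrix(numeric(0), 0, 0)), "empty")
})

test_that("benchmark ranking and selection reproduce the known structure", {
  fit <- gra(yno_bde())
  expect_equal(fit$ranking[1:2], c("E_HOMO", "dH_homo"))
  expect_equal(fit$selected,
               c("dH_homo", "Q_O", "N_X", "alpha_pol", "E_HOMO_m1",
                 "E_HOMO", "E_LUMO", "dE"))
  expect_true(all(fit$degrees > 0 & fit$degrees <= 1))
  # an unreachable threshold selects nothing
  high <- gra(yno_bde(), threshold = 0.99)
  expect_length(high$selected, 0L)
})
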