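test_that("shrinkage intensity vanishes with abundant correlated data", {
  set.seed(51)
  # real correlation structure: the analytic intensity goes to zero and
  # the estimate approaches the sample covariance
  sigma <- 0.5 ^ abs(outer(1:5, 1:5, "-"))
  x <- matrix(rnorm(10000 * 5), 10000, 5) %*% chol(sigma)
  sc <- shrink_covariance(x)
  expect_lt(sc$lambda, 0.05)
  expect_lt(max(abs(sc$sigma - stats::cov(x))), 0.05)
  expect_equal(diag(sc$sigma), apply(x, 2, stats::var),
               ignore_attr = TRUE)

  # independent columns: everything is (correctly) shrunk to the diagonal
  # target, which stays within sampling noise of the sample covariance
  x0 <- matrix(rnorm(10000 * 5), 10000, 5)
  sc0 <- shrink_covariance(x0)
  expect_gt(sc0$lambda, 0.5)
  expect_lt(max(abs(sc0$sigma - stats::cov(x0))), 0.05)
})

test_that("shrinkage keeps the ill-posed regime well conditioned", {
  m <- strong_model(seed = 52)
  d <- simulate_cohort(m, 15, seed = 53)
  sc <- shrink_covariance(d$values)
  expect_true(sc$lambda > 0 && sc$lambda <= 1)
  ev <- eigen(sc$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(sc$sigma), apply(d$values, 2, stats::var),
               ignore_attr = TRUE)
  # lambda is invariant to variable relabeling
  perm <- sample(ncol(d$values))
  expect_equal(shrink_covariance(d$values[, perm])$lambda, sc$lambda)
})

test_that("shrinkage input contracts are enforced", {
  expect_error(shrink_covariance(matrix(rnorm(4), 2, 2)),
               "insufficient samples")
  x <- cbind(rnorm(10), rep(1, 10))
  colnames(x) <- c("a", "b")
  expect_error(shrink_covariance(x), "degenerate variable.*b")
})

test_that("partial correlations match the regression-residual oracle", {
  s <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3)
  net <- partial_correlations(s)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(net$pmat[i, j], oracle_pcor(s, i, j), tolerance = 1e-10)
  expect_equal(diag(net$pmat), rep(1, 3))
  expect_equal(net$pmat, t(net$pmat))

  # random SPD covariances, k = 5
  set.seed(54)
  for (rep in 1:10) {
    a <- matrix(rnorm(25), 5, 5)
    s5 <- crossprod(a) + diag(5)
    p5 <- partial_correlations(s5)$pmat
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(p5[i, j], oracle_pcor(s5, i, j), tolerance = 1e-8)
  }

  # diagonal covariance: isolated nodes
  pd <- partial_correlations(diag(c(1, 2, 3)))$pmat
  expect_true(all(pd[upper.tri(pd)] == 0))
})

test_that("the transform commutes with node permutation and recovers the
           model at scale", {
  m <- strong_model(seed = 55)
  net <- partial_correlations(m$sigma)
  expect_equal(net$pmat, m$pcor_true, tolerance = 1e-8, ignore_attr = TRUE)
  perm <- sample(78)
  net_p <- partial_correlations(m$sigma[perm, perm])
  expect_equal(net_p$pmat, net$pmat[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("classical limit: shrinkage pipeline approaches the exact
           partial correlations for n >> k", {
  set.seed(56)
  a <- matrix(rnorm(25), 5, 5)
  sigma <- crossprod(a) + diag(5)
  x <- matrix(rnorm(10000 * 5), 10000, 5) %*% chol(sigma)
  net <- partial_correlations(shrink_covariance(x))
  expect_lt(max(abs(net$pmat - partial_correlations(sigma)$pmat)), 0.05)
})

test_that("covariate adjustment removes a planted confounder", {
  set.seed(57)
  n <- 4000
  # background covariance keeps the shrinkage intensity small, so the
  # adjustment leakage lambda*(1-lambda)*r is negligible
  d <- simulate_cohort(strong_model(seed = 570), n, seed = 571)
  age <- d$age
  gender <- d$gender
  x <- d$values
  x[, 1] <- 0.5 * age + rnorm(n, sd = 2)
  x[, 2] <- 0.5 * age + rnorm(n, sd = 2)
  expect_gt(stats::cor(x[, 1], x[, 2]), 0.4)          # confounded
  net <- adjust_covariates(x, age, gender)
  expect_equal(dim(net$pmat), c(78, 78))
  expect_lt(abs(net$pmat[1, 2]), 0.1)                  # confounder removed
  expect_error(adjust_covariates(x, rep(60, n), gender),
               "degenerate variable: age")
})

test_that("adjustment is a no-op when covariates are independent", {
  m <- strong_model(seed = 58)
  d <- simulate_cohort(m, 1200, seed = 59)
  raw <- partial_correlations(shrink_covariance(d$values))
  adj <- adjust_covariates(d$values, d$age, d$gender)
  expect_lt(max(abs(raw$pmat - adj$pmat)), 0.02)
})
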