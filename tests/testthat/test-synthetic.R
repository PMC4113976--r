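test_that("build_precision plants edges with exact implied magnitudes", {
  atlas <- default_atlas()

  # no edges: diagonal precision, all implied partial correlations zero
  m0 <- build_precision(atlas, n_edges = 0, seed = 1)
  expect_equal(nrow(m0$true_edges), 0)
  off <- m0$pcor_true; diag(off) <- 0
  expect_true(all(off == 0))

  # a single planted edge at 0.4 is recovered exactly by the transform of
  # the exact model covariance (independent regression-residual oracle)
  m1 <- build_precision(atlas, n_edges = 1,
                        partial_corr_range = c(0.4, 0.4), seed = 2)
  e <- m1$true_edges[1, ]
  expect_equal(abs(m1$pcor_true[e[1], e[2]]), 0.4)
  expect_equal(abs(oracle_pcor(m1$sigma, e[1], e[2])), 0.4,
               tolerance = 1e-10)
  net <- partial_correlations(m1$sigma)
  expect_equal(net$pmat, m1$pcor_true, tolerance = 1e-8,
               ignore_attr = TRUE)

  # general model: SPD, support matches true_edges, magnitudes in range
  m <- build_precision(atlas, n_edges = 100, seed = 3)
  ev <- eigen(m$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  mags <- abs(m$pcor_true[m$true_edges])
  expect_true(all(mags >= 0.3 - 1e-12 & mags <= 0.5 + 1e-12))
  support <- which(upper.tri(m$pcor_true) & m$pcor_true != 0,
                   arr.ind = TRUE)
  expect_equal(nrow(support), 100)
  expect_setequal(edge_key(support[, 1], support[, 2]),
                  edge_key(m$true_edges[, 1], m$true_edges[, 2]))

  # infeasible request errors out
  expect_error(build_precision(atlas, n_edges = 100,
                               partial_corr_range = c(0.8, 0.9), seed = 1),
               "model-construction error")
})

test_that("simulated cohorts are reproducible and match the model", {
  m <- build_precision(default_atlas(), n_edges = 30, seed = 4)
  d1 <- simulate_cohort(m, 15, seed = 7)
  d2 <- simulate_cohort(m, 15, seed = 7)
  expect_identical(d1$values, d2$values)
  expect_identical(d1$age, d2$age)
  d3 <- simulate_cohort(m, 15, seed = 8)
  expect_false(identical(d1$values, d3$values))
  expect_equal(dim(d1$values), c(15, 78))
  expect_false(anyNA(d1$values))
  expect_true(all(d1$age >= 55 & d1$age <= 80))
  expect_true(all(d1$gender %in% 0:1))

  # large-sample consistency: sample correlations approach the model's
  # (n large enough that the max deviation over 3003 entries clears the
  # bound with margin)
  big <- simulate_cohort(m, 8000, seed = 9)
  model_cor <- stats::cov2cor(m$sigma)
  expect_lt(max(abs(stats::cor(big$values) - model_cor)), 0.05)
})

test_that("asymmetry offsets produce the closed-form laterality score", {
  atlas <- default_atlas()
  m <- build_precision(atlas, n_edges = 0, seed = 5,
                       regional_means = rep(40, 78), noise_sd = 1)
  # +2 MTR% on the left member of the first homotopic pair:
  # population laterality = 2 / 82
  offs <- c(2, rep(0, 38))
  d <- simulate_cohort(m, 4000, asymmetry = offs, seed = 11)
  ls <- laterality_scores(d)
  expect_lt(abs(mean(ls[, 1]) - 2 / 82), 0.001)
  expect_lt(abs(mean(ls[, 2])), 0.001)
})

test_that("covariate effects shift the simulated values linearly", {
  m <- build_precision(default_atlas(), n_edges = 0, seed = 6,
                       regional_means = rep(40, 78), noise_sd = 1)
  eff <- list(age = c(0.5, rep(0, 77)), gender = c(0, 3, rep(0, 76)))
  d <- simulate_cohort(m, 600, covariate_effect = eff, seed = 12)
  fit1 <- stats::lm(d$values[, 1] ~ d$age + d$gender)
  fit2 <- stats::lm(d$values[, 2] ~ d$age + d$gender)
  expect_equal(unname(coef(fit1)["d$age"]), 0.5, tolerance = 0.05)
  expect_equal(unname(coef(fit2)["d$gender"]), 3, tolerance = 0.3)
})

test_that("two-group scenarios modify the support as requested", {
  base <- strong_model(seed = 13)
  te <- base$true_edges

  # identity case: no modification shares the population model
  sc0 <- two_group_scenario(base, NULL, NULL, n_per_group = 5, seed = 1)
  expect_equal(sc0$model_ad$pcor_true, base$pcor_true)

  lost <- te[1:3, , drop = FALSE]
  free <- which(upper.tri(base$omega) & base$pcor_true == 0, arr.ind = TRUE)
  gained <- free[c(10, 500), , drop = FALSE]
  sc <- two_group_scenario(base, lost, gained, gained_weights = 0.3,
                           n_per_group = 5, seed = 2)
  pc2 <- sc$model_ad$pcor_true
  expect_true(all(pc2[lost] == 0))
  expect_true(all(pc2[gained] == 0.3))
  expect_equal(nrow(sc$model_ad$true_edges), nrow(te) - 3 + 2)
  expect_equal(unique(sc$control$group), "control")
  expect_equal(unique(sc$ad$group), "AD")

  # contract violations
  expect_error(two_group_scenario(base, matrix(c(free[1, 1], free[1, 2]),
                                               1, 2), NULL),
               "subset")
  expect_error(two_group_scenario(base, NULL, te[1, , drop = FALSE]),
               "disjoint")
  expect_error(two_group_scenario(base, NULL, gained, gained_weights = 0),
               "nonzero")
})

test_that("dataset TSV round trip is lossless up to numeric formatting", {
  m <- build_precision(default_atlas(), n_edges = 10, seed = 14)
  d <- simulate_cohort(m, 8, seed = 15)
  vp <- tempfile(fileext = ".tsv"); cp <- tempfile(fileext = ".tsv")
  write_mtr_dataset(d, vp, cp)
  back <- read_mtr_dataset(vp, cp)
  expect_equal(back$values, d$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$group, d$group)
  expect_equal(back$age, d$age, tolerance = 1e-6)
})
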