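test_that("mixture fit recovers the null proportion on direct samples", {
  set.seed(61)
  # pure Hotelling null
  x <- rhotelling(3003, 800)
  fit <- fit_mixture(x, "hotelling")
  expect_gte(fit$eta0, 0.95)
  expect_lte(fit$eta0, 1)
  expect_equal(1 / sqrt(fit$kappa), 1 / sqrt(800), tolerance = 0.15)

  # 5% clearly separated alternatives
  etas <- replicate(10, {
    v <- c(rhotelling(2853, 800),
           runif(150, 0.25, 0.6) * sample(c(-1, 1), 150, TRUE))
    fit_mixture(v, "hotelling")$eta0
  })
  expect_equal(mean(etas), 0.95, tolerance = 0.03)

  expect_error(fit_mixture(rep(0.1, 500)), "degenerate distribution")
  expect_error(fit_mixture(rnorm(50)), "at least 100")
})

test_that("lfdr values are capped, monotone, and maximal at zero", {
  set.seed(62)
  v <- c(0, rhotelling(2000, 500), runif(60, 0.3, 0.5))
  fit <- fit_mixture(v, "hotelling")
  lf <- edge_lfdr(fit, v)
  expect_true(all(lf >= 0 & lf <= 1))
  expect_equal(lf[1], 1)                      # center of the null
  o <- order(abs(v))
  expect_true(all(diff(lf[o]) <= 1e-12))      # non-increasing in |p|
})

test_that("edge calling respects thresholds, nestedness and sign flips", {
  m <- strong_model(seed = 63)
  d <- simulate_cohort(m, 30, seed = 64)
  net <- estimate_network(d, adjust = FALSE)
  es2 <- call_edges(net, 0.2)
  es5 <- call_edges(net, 0.5)
  expect_gt(nrow(es2$edges), 0)
  expect_true(all(es2$edges$lfdr < 0.2))
  k2 <- edge_key(es2$edges$i, es2$edges$j)
  k5 <- edge_key(es5$edges$i, es5$edges$j)
  expect_true(all(k2 %in% k5))                # nestedness
  expect_equal(sum(es2$disconnected),
               78 - length(unique(c(es2$edges$i, es2$edges$j))))
  # counts by class sum to the total
  expect_equal(sum(table(es2$edges$class)), nrow(es2$edges))

  # global sign flip of the data leaves the calls unchanged
  d_flipped <- d
  d_flipped$values <- -d$values
  net_f <- estimate_network(d_flipped, adjust = FALSE)
  es_f <- call_edges(net_f, 0.2)
  expect_setequal(edge_key(es_f$edges$i, es_f$edges$j), k2)

  # an all-null lfdr matrix produces an empty set with 78 isolated nodes
  net0 <- net
  net0$lfdr <- matrix(1, 78, 78)
  es0 <- call_edges(net0, 0.2)
  expect_equal(nrow(es0$edges), 0)
  expect_equal(sum(es0$disconnected), 78)
})

test_that("group comparison uses the Fisher-z construction", {
  # closed form: p_a = 0.5, p_b = 0, n = 15 each =>
  # z = atanh(0.5) / sqrt(2/12) = 1.3457
  pa <- diag(78); pb <- diag(78)
  pa[1, 2] <- pa[2, 1] <- 0.5
  net_a <- structure(list(pmat = pa, lfdr = NULL, n = 15, lambda = 0.5,
                          atlas = default_atlas(), group = "Controls"),
                     class = "pcor_network")
  net_b <- net_a; net_b$pmat <- pb; net_b$group <- "AD"
  es <- compare_groups(net_b, net_a, n_a = 15, n_b = 15)
  expect_equal(es$zmat[1, 2], -atanh(0.5) / sqrt(2 / 12),
               tolerance = 1e-4, ignore_attr = TRUE)

  # identical networks: no differential edges
  es_id <- compare_groups(net_a, net_a)
  expect_equal(nrow(es_id$edges), 0)

  # incompatible node sets refuse to compare
  small <- net_a; small$pmat <- diag(10); small$atlas <- NULL
  expect_error(compare_groups(net_a, small), "incompatible")
})

test_that("a lost edge is recovered by the differential test at n = 500", {
  hits <- 0L
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    base <- strong_model(seed = 70 + r)
    lost <- base$true_edges[1, , drop = FALSE]
    sc <- two_group_scenario(base, lost_edges = lost, n_per_group = 500,
                             seed = 700 + r)
    net_c <- estimate_network(sc$control, adjust = FALSE)
    net_a <- estimate_network(sc$ad, adjust = FALSE)
    es <- compare_groups(net_a, net_c, threshold = 0.2)
    key <- edge_key(lost[1], lost[2])
    found <- nrow(es$edges) > 0 &&
      key %in% edge_key(es$edges$i, es$edges$j)
    dir_ok <- found &&
      es$edges$direction[edge_key(es$edges$i, es$edges$j) == key] ==
        "AD<control"
    if (found && dir_ok) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("hemisphere comparison maps the 741 homotopic edge pairs", {
  m <- strong_model(seed = 81)
  d <- simulate_cohort(m, 30, seed = 82)
  net <- estimate_network(d, adjust = FALSE)
  es <- compare_hemispheres(net)
  expect_equal(length(es$z), 741)
  expect_equal(nrow(es$lh_pairs), 741)
  expect_true(all(es$lh_pairs <= 39))
  if (nrow(es$edges) > 0)
    expect_true(all(es$edges$direction %in% c("LH>RH", "LH<RH")))
})

# mirror-symmetric background (6 bilateral edges) with an optional extra
# left-only edge; background covariance keeps the shrinkage intensity
# away from 1 so the estimated networks carry usable structure
mirror_model <- function(extra_lh_edge = FALSE) {
  atlas <- default_atlas()
  pc <- matrix(0, 78, 78)
  for (e in list(c(1, 5), c(7, 12), c(14, 22), c(25, 30), c(31, 38),
                 c(3, 18))) {
    pc[e[1], e[2]] <- pc[e[2], e[1]] <- 0.45
    pc[e[1] + 39, e[2] + 39] <- pc[e[2] + 39, e[1] + 39] <- 0.45
  }
  if (extra_lh_edge) pc[2, 9] <- pc[9, 2] <- 0.5
  m <- build_precision(atlas, n_edges = 0, seed = 95)
  m$omega <- diag(78) - pc
  m$sigma <- chol2inv(chol(m$omega))
  m$pcor_true <- pc + diag(78)
  m
}

test_that("a left-lateralized edge is flagged LH>RH at n = 500", {
  m <- mirror_model(extra_lh_edge = TRUE)
  hits <- 0L
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    d <- simulate_cohort(m, 500, seed = 900 + r)
    net <- estimate_network(d, adjust = FALSE)
    es <- compare_hemispheres(net)
    hit <- nrow(es$edges) > 0 &&
      any(es$edges$i == 2 & es$edges$j == 9 &
            es$edges$direction == "LH>RH")
    if (hit) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("mirror-symmetric models show no systematic edge asymmetry", {
  m <- mirror_model()
  counts <- vapply(1:8, function(r) {
    d <- simulate_cohort(m, 400, seed = 950 + r)
    net <- estimate_network(d, adjust = FALSE)
    nrow(compare_hemispheres(net)$edges)
  }, numeric(1))
  # false flags stay rare relative to the 741 tested pairs
  expect_lt(mean(counts), 741 * 0.02)
})

test_that("Jarque-Bera statistic follows its chi-squared null", {
  set.seed(99)
  expect_gt(jarque_bera(rnorm(3000))$p.value, 0.001)
  expect_lt(jarque_bera(rexp(3000))$p.value, 1e-6)
  ps <- replicate(30, jarque_bera(rnorm(1000))$p.value)
  expect_gt(mean(ps > 0.05), 0.7)
})
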