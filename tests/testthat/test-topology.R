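make_net <- function(seed = 111, n = 30) {
  m <- strong_model(seed = seed)
  d <- simulate_cohort(m, n, seed = seed + 1)
  estimate_network(d, adjust = FALSE)
}

test_that("binarization modes agree with their contracts", {
  net <- make_net()
  full <- binarize(net, density = 1)
  expect_equal(full$n_edges, 3003)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)] == 1))
  expect_equal(diag(full$adjacency), rep(0L, 78), ignore_attr = TRUE)

  b2 <- binarize(net, lfdr = 0.2)
  b5 <- binarize(net, lfdr = 0.5)
  expect_gte(b5$n_edges, b2$n_edges)
  expect_true(all(b5$adjacency[b2$adjacency == 1] == 1))  # nested

  bd <- binarize(net, density = 0.05)
  expect_equal(bd$n_edges, round(0.05 * 3003))
  expect_error(binarize(net, density = 1.5), "density")
  expect_error(binarize(net), "exactly one")
  expect_error(binarize(net, lfdr = 0.2, density = 0.1), "exactly one")
})

test_that("degrees and the hub rule follow their definitions", {
  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- 1L; star <- star + t(star)
  expect_equal(degrees(star), c(5, 1, 1, 1, 1, 1))

  # 78 all-distinct integrated degrees: >= 75th percentile keeps 20 nodes
  h <- hubs(1:78)
  expect_equal(length(h$hubs), 20)
  expect_false(h$degenerate)
  expect_setequal(h$hubs, 59:78)

  # regular graph: everyone meets the cutoff, flagged degenerate
  h2 <- hubs(rep(4, 10))
  expect_equal(length(h2$hubs), 10)
  expect_true(h2$degenerate)
})

test_that("efficiencies match hand-derived values", {
  k5 <- matrix(1L, 5, 5); diag(k5) <- 0L
  expect_equal(global_efficiency(k5), 1)
  expect_equal(local_efficiency(k5), 1)

  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 3] <- 1L; path3 <- path3 + t(path3)
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)

  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- 1L; star <- star + t(star)
  expect_equal(local_efficiency(star), 0)

  empty <- matrix(0L, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  expect_equal(local_efficiency(empty), 0)
})

test_that("efficiency and degree agree with brute-force oracles on random
           graphs", {
  set.seed(112)
  for (n in c(6, 7)) {
    for (r in 1:25) {
      a <- random_adjacency(n, runif(1, 0.15, 0.8))
      expect_equal(global_efficiency(a), oracle_efficiency(a),
                   tolerance = 1e-12)
      expect_equal(local_efficiency(a), oracle_local_efficiency(a),
                   tolerance = 1e-12)
      expect_equal(shortest_paths(a), fw_distances(a))
    }
  }
})

test_that("modularity matches direct evaluation and known graphs", {
  # two disjoint triangles under the natural partition: Q = 0.5
  tri2 <- matrix(0L, 6, 6)
  tri2[1, 2] <- tri2[2, 3] <- tri2[1, 3] <- 1L
  tri2[4, 5] <- tri2[5, 6] <- tri2[4, 6] <- 1L
  tri2 <- tri2 + t(tri2)
  expect_equal(modularity_q(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # a single module always has Q = 0
  expect_equal(modularity_q(tri2, rep(1, 6)), 0)
  expect_error(modularity_q(tri2, c(1, 1, 1)), "partition")

  set.seed(113)
  for (r in 1:20) {
    a <- random_adjacency(6, 0.5)
    part <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_q(a, part), oracle_q(a, part),
                 tolerance = 1e-12)
    expect_lte(modularity_q(a, part), 1)
  }
})

test_that("greedy partition search approaches the exhaustive maximum", {
  set.seed(114)
  for (r in 1:10) {
    a <- random_adjacency(5, 0.5)
    if (sum(a) == 0) next
    bp <- best_partition(a)
    qmax <- oracle_best_q(a)
    expect_lte(bp$Q, qmax + 1e-12)
    expect_gte(bp$Q, qmax - 0.15)  # greedy search is near-optimal here
    expect_equal(modularity_q(a, bp$partition), bp$Q)
  }
  # two cliques joined by one edge: the natural split is found exactly
  a <- matrix(0L, 8, 8)
  a[1:4, 1:4] <- 1L; a[5:8, 5:8] <- 1L; diag(a) <- 0L
  a[4, 5] <- a[5, 4] <- 1L
  bp <- best_partition(a)
  expect_equal(length(unique(bp$partition)), 2)
  expect_equal(bp$partition[1:4], rep(bp$partition[1], 4))
})

test_that("density integration averages the per-density metric values", {
  net <- make_net(seed = 115)
  gi <- integrate_over_densities(net, "GE", n_points = 8)
  expect_length(gi$per_density, 8)
  expect_gte(gi$value, min(gi$per_density))
  expect_lte(gi$value, max(gi$per_density))
  expect_equal(gi$value, mean(gi$per_density))
  # node count constant => integrated "metric" equals the constant
  const <- integrate_over_densities(net, function(bn) 78, n_points = 5)
  expect_equal(const$value, 78)
  # degenerate band warns and returns a single density
  net0 <- net
  net0$lfdr <- matrix(1, 78, 78)
  expect_warning(r0 <- integrate_over_densities(net0, "GE"), "degenerate")
  expect_length(r0$densities, 1)
})

test_that("topology report integrates metrics and flags hubs", {
  net <- make_net(seed = 116)
  tr <- topology_report(net, n_points = 10)
  expect_true(all(tr$integrated >= 0))
  expect_lte(tr$integrated["GE"], 1)
  expect_lte(tr$integrated["LE"], 1)
  expect_equal(nrow(tr$curves), 10)
  expect_true(all(tr$integrated_degree >= 0))
  expect_gte(length(tr$hubs), 78 / 4)
  # GE curves are non-decreasing in density (nested binarizations)
  expect_true(all(diff(tr$curves$GE) >= -1e-12))
})

test_that("density-matched comparison returns one metric pair per
           density", {
  net_a <- make_net(seed = 117)
  net_b <- make_net(seed = 118)
  grid <- seq(0.02, 0.1, length.out = 5)
  cmp <- compare_density_matched(net_a, net_b, grid, "GE")
  expect_equal(nrow(cmp), 5)
  self <- compare_density_matched(net_a, net_a, grid, "GE")
  expect_equal(self$value_a, self$value_b)
  expect_true(all(diff(cmp$value_a) >= -1e-12))
})

test_that("permutation metric test honors its contracts", {
  m <- strong_model(seed = 119)
  sc <- two_group_scenario(m, n_per_group = 10, seed = 120)
  res <- permutation_metric_test(sc$control, sc$ad, n_perm = 100,
                                 n_points = 4, seed = 121)
  expect_equal(res$metric, c("GE", "LE", "Q"))
  expect_true(all(res$p >= 1 / 101))
  expect_true(all(res$p <= 1))
  small <- sc$control
  small$values <- small$values[1:2, ]
  small$age <- small$age[1:2]; small$gender <- small$gender[1:2]
  small$group <- small$group[1:2]
  expect_error(permutation_metric_test(small, sc$ad, n_perm = 100),
               "insufficient samples")
})
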