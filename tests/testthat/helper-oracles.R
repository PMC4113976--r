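# Independent brute-force oracles used across the suite. These must stay
# independent of the package implementations they check.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (m in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
  d
}

# efficiency from the distance matrix: mean over ordered pairs of 1/d
oracle_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- fw_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_efficiency(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# direct evaluation of Newman's Q for a partition
oracle_q <- function(a, partition) {
  m2 <- sum(a)
  if (m2 == 0) return(0)
  q <- 0
  for (c in unique(partition)) {
    idx <- partition == c
    q <- q + sum(a[idx, idx]) / m2 - (sum(a[idx, ]) / m2)^2
  }
  q
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# maximum modularity by exhaustive search over all partitions
oracle_best_q <- function(a) {
  parts <- all_partitions(nrow(a))
  max(vapply(parts, function(p) oracle_q(a, p), numeric(1)))
}

# classical partial correlation of variables i and j given the rest,
# computed from a covariance matrix by the regression-residual route:
# correlate the residual (co)variances after projecting out the others
oracle_pcor <- function(sigma, i, j) {
  rest <- setdiff(seq_len(ncol(sigma)), c(i, j))
  if (length(rest) == 0) {
    return(sigma[i, j] / sqrt(sigma[i, i] * sigma[j, j]))
  }
  s_aa <- sigma[c(i, j), c(i, j)]
  s_ab <- sigma[c(i, j), rest, drop = FALSE]
  s_bb <- sigma[rest, rest, drop = FALSE]
  cond <- s_aa - s_ab %*% solve(s_bb, t(s_ab))
  cond[1, 2] / sqrt(cond[1, 1] * cond[2, 2])
}

# random symmetric 0/1 adjacency with given edge probability
random_adjacency <- function(n, p_edge) {
  a <- matrix(0L, n, n)
  iu <- which(upper.tri(a), arr.ind = TRUE)
  keep <- runif(nrow(iu)) < p_edge
  a[iu[keep, , drop = FALSE]] <- 1L
  a + t(a)
}

# enumerate every labeled graph on n nodes (n small)
all_graphs <- function(n) {
  npairs <- n * (n - 1) / 2
  iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lapply(0:(2^npairs - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npairs)]
    a <- matrix(0L, n, n)
    a[iu[bits == 1, , drop = FALSE]] <- 1L
    a + t(a)
  })
}

# exact Hotelling-null sample: p with p^2 ~ Beta(1/2, (kappa-1)/2)
rhotelling <- function(n, kappa) {
  sqrt(rbeta(n, 0.5, (kappa - 1) / 2)) * sample(c(-1, 1), n, replace = TRUE)
}

# strong-covariance scenario: fewer, stronger edges so that edge calling
# and the density band are exercised on non-empty networks
strong_model <- function(seed = 1, n_edges = 50,
                         range = c(0.4, 0.7)) {
  build_precision(default_atlas(), n_edges = n_edges,
                  partial_corr_range = range, seed = seed)
}

edge_key <- function(i, j, k = 78) (pmin(i, j) - 1) * k + pmax(i, j)
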