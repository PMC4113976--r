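#' Binarize a partial-correlation network
#'
#' Two modes. \code{lfdr} mode keeps the edges whose lfdr is below a
#' threshold. \code{density} mode keeps the \code{round(density * n_pairs)}
#' edges of smallest lfdr (ties broken by larger partial-correlation
#' magnitude, then by node-index order); this is the construction used for
#' density-matched comparisons and density integration.
#'
#' @param network a \code{pcor_network} with its lfdr matrix filled.
#' @param lfdr lfdr threshold (lfdr mode).
#' @param density target edge density in (0, 1] (density mode). Exactly
#'   one of \code{lfdr} and \code{density} must be given.
#' @return object of class \code{binary_network}: list with
#'   \code{adjacency} (k x k 0/1 matrix, zero diagonal), \code{density},
#'   \code{n_edges}, \code{mode}, \code{threshold}.
#' @export
binarize <- function(network, lfdr = NULL, density = NULL) {
  stopifnot(inherits(network, "pcor_network"))
  if (is.null(network$lfdr)) stop("network has no lfdr matrix")
  if (is.null(lfdr) == is.null(density))
    stop("give exactly one of lfdr= or density=")
  k <- ncol(network$pmat)
  iu <- which(upper.tri(network$pmat), arr.ind = TRUE)
  lf <- network$lfdr[iu]
  n_pairs <- nrow(iu)
  if (!is.null(lfdr)) {
    keep <- lf < lfdr
    mode <- "lfdr"; thr <- lfdr
  } else {
    if (density <= 0 || density > 1)
      stop("density must be in (0, 1]")
    m <- round(density * n_pairs)
    if (m > n_pairs) stop("density demands more edges than pairs")
    ord <- order(lf, -abs(network$pmat[iu]), iu[, 1], iu[, 2])
    keep <- logical(n_pairs)
    if (m > 0) keep[ord[seq_len(m)]] <- TRUE
    mode <- "density"; thr <- density
  }
  a <- matrix(0L, k, k)
  a[iu[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  dimnames(a) <- dimnames(network$pmat)
  structure(
    list(adjacency = a, density = sum(keep) / n_pairs,
         n_edges = sum(keep), mode = mode, threshold = thr,
         atlas = network$atlas),
    class = "binary_network"
  )
}

#' Construct a binary network from an adjacency matrix
#'
#' @param a symmetric 0/1 matrix with zero diagonal.
#' @return \code{binary_network}.
#' @export
binary_network <- function(a) {
  a <- as.matrix(a)
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("self-loops are not allowed")
  if (!all(a %in% c(0, 1))) stop("adjacency must be 0/1")
  storage.mode(a) <- "integer"
  k <- ncol(a)
  structure(
    list(adjacency = a, density = sum(a) / (k * (k - 1)),
         n_edges = sum(a) / 2, mode = "direct", threshold = NA),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary network: %d nodes, %d edges (density %.4f)\n",
              ncol(x$adjacency), x$n_edges, x$density))
  invisible(x)
}

#' Node degrees
#'
#' \eqn{k_i = \sum_j a_{ij}}: the number of edges incident to each node.
#'
#' @param a a \code{binary_network} (or adjacency matrix).
#' @return integer vector of degrees.
#' @export
degrees <- function(a) {
  if (inherits(a, "binary_network")) a <- a$adjacency
  colSums(a)
}

#' Hub nodes from integrated degrees
#'
#' Hubs are the nodes whose (density-integrated) degree lies in the upper
#' quartile of the degree distribution, i.e. is at least the 75th
#' percentile (linear-interpolation definition).
#'
#' @param integrated_degrees numeric vector of integrated node degrees.
#' @return list with \code{hubs} (indices), \code{cutoff}, and
#'   \code{degenerate} (TRUE when all degrees are equal, in which case
#'   every node meets the threshold).
#' @export
hubs <- function(integrated_degrees) {
  cutoff <- stats::quantile(integrated_degrees, 0.75, names = FALSE)
  idx <- which(integrated_degrees >= cutoff)
  list(hubs = idx, cutoff = cutoff,
       degenerate = length(unique(integrated_degrees)) == 1)
}

#' Global efficiency
#'
#' Mean over node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing zero; 1 for a complete graph.
#'
#' @param a a \code{binary_network} or 0/1 adjacency matrix.
#' @return efficiency in [0, 1].
#' @export
global_efficiency <- function(a) {
  if (inherits(a, "binary_network")) a <- a$adjacency
  storage.mode(a) <- "integer"
  cpp_global_efficiency(a)
}

#' Local efficiency
#'
#' Mean over nodes of the efficiency of the subgraph induced by each
#' node's neighbors; nodes with fewer than two neighbors contribute zero.
#'
#' @param a a \code{binary_network} or 0/1 adjacency matrix.
#' @return local efficiency in [0, 1].
#' @export
local_efficiency <- function(a) {
  if (inherits(a, "binary_network")) a <- a$adjacency
  storage.mode(a) <- "integer"
  cpp_local_efficiency(a)
}

#' Shortest-path length matrix
#'
#' Breadth-first-search geodesic distances; \code{Inf} for disconnected
#' pairs.
#'
#' @param a a \code{binary_network} or 0/1 adjacency matrix.
#' @return k x k numeric matrix.
#' @export
shortest_paths <- function(a) {
  if (inherits(a, "binary_network")) a <- a$adjacency
  storage.mode(a) <- "integer"
  cpp_shortest_paths(a)
}

#' Newman modularity of a partition
#'
#' \eqn{Q = \sum_c (e_{cc} - a_c^2)} where \eqn{e_{cc}} is the fraction of
#' edges inside module c and \eqn{a_c} the fraction of edge endpoints in
#' c.
#'
#' @param a a \code{binary_network} or adjacency matrix.
#' @param partition integer/character module label per node.
#' @return Q (<= 1); 0 for a single module or an empty graph.
#' @export
modularity_q <- function(a, partition) {
  if (inherits(a, "binary_network")) a <- a$adjacency
  k <- ncol(a)
  if (length(partition) != k)
    stop("argument error: partition must cover all nodes")
  m2 <- sum(a)                      # 2 * edge count
  if (m2 == 0) return(0)
  labs <- unique(partition)
  q <- 0
  for (c in labs) {
    idx <- which(partition == c)
    e_cc <- sum(a[idx, idx]) / m2
    a_c <- sum(a[idx, ]) / m2
    q <- q + e_cc - a_c^2
  }
  q
}

#' Modularity-maximizing partition (greedy agglomerative)
#'
#' Greedy agglomerative Q maximization (Clauset-Newman-Moore, via
#' igraph's fast-greedy community detection). Deterministic; the seed
#' argument is accepted for interface stability.
#'
#' @param a a \code{binary_network} or adjacency matrix.
#' @param seed unused (the search is deterministic).
#' @return list with \code{partition} (integer labels) and \code{Q}.
#' @export
best_partition <- function(a, seed = 1L) {
  if (inherits(a, "binary_network")) a <- a$adjacency
  k <- ncol(a)
  if (sum(a) == 0)
    return(list(partition = seq_len(k), Q = 0))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  cm <- igraph::cluster_fast_greedy(g)
  part <- as.integer(igraph::membership(cm))
  list(partition = part, Q = modularity_q(a, part))
}

#' Densities delimiting the lfdr band
#'
#' Maps lfdr thresholds to edge densities: the density at threshold t is
#' the fraction of node pairs with lfdr < t.
#'
#' @param network a \code{pcor_network} with lfdr filled.
#' @param lfdr_band length-2 vector of lfdr thresholds (default
#'   c(0.2, 0.5)).
#' @return length-2 numeric vector of densities.
#' @export
density_band <- function(network, lfdr_band = c(0.2, 0.5)) {
  if (is.null(network$lfdr)) stop("network has no lfdr matrix")
  lf <- upper_vals(network$lfdr)
  c(mean(lf < lfdr_band[1]), mean(lf < lfdr_band[2]))
}

metric_fun <- function(metric) {
  switch(metric,
         GE = function(bn) global_efficiency(bn),
         LE = function(bn) local_efficiency(bn),
         Q = function(bn) best_partition(bn)$Q,
         degree = function(bn) degrees(bn),
         stop("unknown metric: ", metric))
}

#' Integrate a graph metric over a density band
#'
#' Evaluates the metric on binarized networks at \code{n_points} evenly
#' spaced densities between the densities reached at the lfdr-band
#' endpoints, and averages with equal weights (all densities treated as
#' equally likely).
#'
#' @param network a \code{pcor_network} with lfdr filled.
#' @param metric one of "GE", "LE", "Q", "degree", or a function of a
#'   \code{binary_network}.
#' @param lfdr_band lfdr interval defining the density range (default
#'   c(0.2, 0.5)).
#' @param n_points number of grid densities (default 30).
#' @return list with \code{value} (the integrated metric; a vector for
#'   "degree"), \code{densities}, \code{per_density} (metric value(s) per
#'   grid density), and \code{degenerate} (TRUE when the band collapses
#'   to one density).
#' @export
integrate_over_densities <- function(network, metric = "GE",
                                     lfdr_band = c(0.2, 0.5),
                                     n_points = 30) {
  fn <- if (is.function(metric)) metric else metric_fun(metric)
  band <- density_band(network, lfdr_band)
  degenerate <- band[1] == band[2]
  if (degenerate) {
    warning("degenerate density band: single density used")
    grid <- band[1]
  } else {
    grid <- seq(band[1], band[2], length.out = n_points)
  }
  vals <- lapply(grid, function(d) {
    if (d <= 0) {
      bn <- binary_network(matrix(0L, ncol(network$pmat),
                                  ncol(network$pmat)))
    } else {
      bn <- binarize(network, density = d)
    }
    fn(bn)
  })
  if (length(vals[[1]]) > 1) {
    per <- do.call(cbind, vals)
    value <- rowMeans(per)
  } else {
    per <- unlist(vals)
    value <- mean(per)
  }
  list(value = value, densities = grid, per_density = per,
       degenerate = degenerate)
}

#' Full topology report for one network
#'
#' Per-density curves and density-integrated values of global efficiency,
#' local efficiency and modularity, plus integrated node degrees and the
#' hub set.
#'
#' @param network a \code{pcor_network} with lfdr filled.
#' @param lfdr_band,n_points see \code{\link{integrate_over_densities}}.
#' @return object of class \code{topology_report}.
#' @export
topology_report <- function(network, lfdr_band = c(0.2, 0.5),
                            n_points = 30) {
  ge <- integrate_over_densities(network, "GE", lfdr_band, n_points)
  le <- integrate_over_densities(network, "LE", lfdr_band, n_points)
  q <- integrate_over_densities(network, "Q", lfdr_band, n_points)
  dg <- integrate_over_densities(network, "degree", lfdr_band, n_points)
  hb <- hubs(dg$value)
  labels <- if (!is.null(network$atlas)) network$atlas$rois$label else NULL
  structure(
    list(integrated = c(GE = ge$value, LE = le$value, Q = q$value),
         densities = ge$densities,
         curves = data.frame(density = ge$densities, GE = ge$per_density,
                             LE = le$per_density, Q = q$per_density),
         integrated_degree = dg$value,
         hubs = hb$hubs,
         hub_labels = if (!is.null(labels)) labels[hb$hubs] else NULL,
         hub_cutoff = hb$cutoff,
         group = network$group),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat("topology report")
  if (!is.null(x$group)) cat(" (", x$group, ")", sep = "")
  cat(":\n")
  cat(sprintf("  integrated GE = %.4f, LE = %.4f, Q = %.4f\n",
              x$integrated["GE"], x$integrated["LE"], x$integrated["Q"]))
  cat(sprintf("  density range %.4f-%.4f over %d points\n",
              min(x$densities), max(x$densities), length(x$densities)))
  cat("  hubs:", length(x$hubs), "\n")
  invisible(x)
}

# shrinkage -> lfdr -> density-integrated metrics for one group
group_integrated_metrics <- function(x, age, gender, adjust = TRUE,
                                     lfdr_band = c(0.2, 0.5),
                                     n_points = 10,
                                     metrics = c("GE", "LE", "Q")) {
  net <- if (adjust) adjust_covariates(x, age, gender)
         else partial_correlations(shrink_covariance(x))
  fit <- fit_mixture(upper_vals(net$pmat), null_family = "hotelling")
  net$lfdr <- edge_lfdr(fit, net$pmat)
  out <- vapply(metrics, function(m)
    suppressWarnings(
      integrate_over_densities(net, m, lfdr_band, n_points)$value),
    numeric(1))
  names(out) <- metrics
  out
}

#' Permutation test of density-integrated metrics between groups
#'
#' Pools the subjects of two datasets and reshuffles the group labels
#' (preserving group sizes); at each shuffle the full pipeline --
#' covariate-adjusted shrinkage partial correlations, lfdr mixture,
#' binarization over the density band, metric evaluation, density
#' integration -- is re-run for both pseudo-groups. Two-sided p-values
#' are the fraction of permutations whose absolute metric difference is
#' at least the observed one, with the +1 correction.
#'
#' @param data_a,data_b \code{mtr_dataset}s sharing an atlas.
#' @param metrics metric names among "GE", "LE", "Q".
#' @param n_perm number of label shuffles (default 10000).
#' @param lfdr_band,n_points density-integration parameters (a coarser
#'   grid than the per-network report is adequate here).
#' @param adjust adjust for age/gender (default TRUE).
#' @param seed integer seed.
#' @return data.frame with one row per metric: observed group values,
#'   difference, and permutation p.
#' @export
permutation_metric_test <- function(data_a, data_b,
                                    metrics = c("GE", "LE", "Q"),
                                    n_perm = 10000,
                                    lfdr_band = c(0.2, 0.5),
                                    n_points = 10, adjust = TRUE,
                                    seed = 1L) {
  stopifnot(inherits(data_a, "mtr_dataset"), inherits(data_b, "mtr_dataset"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  n_a <- nrow(data_a$values); n_b <- nrow(data_b$values)
  if (n_a < 3 || n_b < 3) stop("insufficient samples: need >= 3 per group")
  x <- rbind(data_a$values, data_b$values)
  age <- c(data_a$age, data_b$age)
  gender <- c(data_a$gender, data_b$gender)
  idx_a <- seq_len(n_a)

  eval_split <- function(ia) {
    ib <- setdiff(seq_len(n_a + n_b), ia)
    ma <- group_integrated_metrics(x[ia, , drop = FALSE], age[ia],
                                   gender[ia], adjust, lfdr_band,
                                   n_points, metrics)
    mb <- group_integrated_metrics(x[ib, , drop = FALSE], age[ib],
                                   gender[ib], adjust, lfdr_band,
                                   n_points, metrics)
    list(a = ma, b = mb, diff = ma - mb)
  }
  obs <- eval_split(idx_a)
  perm_diffs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      eval_split(sample.int(n_a + n_b, n_a))$diff
    }, numeric(length(metrics)))
  })
  if (is.null(dim(perm_diffs)))
    perm_diffs <- matrix(perm_diffs, nrow = length(metrics))
  p <- vapply(seq_along(metrics), function(i)
    (1 + sum(abs(perm_diffs[i, ]) >= abs(obs$diff[i]))) / (1 + n_perm),
    numeric(1))
  data.frame(metric = metrics, value_a = obs$a, value_b = obs$b,
             difference = obs$diff, p = p, row.names = NULL)
}

#' Density-matched metric comparison
#'
#' Binarizes two networks to the same grid of densities and evaluates a
#' metric on each, disentangling topology from edge-count differences.
#' Per-density flags require a multiple-comparison correction downstream;
#' none is applied here.
#'
#' @param net_a,net_b \code{pcor_network}s with lfdr filled.
#' @param density_grid vector of densities.
#' @param metric "GE", "LE" or "Q" (or a function).
#' @return data.frame with columns density, value_a, value_b.
#' @export
compare_density_matched <- function(net_a, net_b, density_grid,
                                    metric = "GE") {
  fn <- if (is.function(metric)) metric else metric_fun(metric)
  va <- vapply(density_grid, function(d) fn(binarize(net_a, density = d)),
               numeric(1))
  vb <- vapply(density_grid, function(d) fn(binarize(net_b, density = d)),
               numeric(1))
  data.frame(density = density_grid, value_a = va, value_b = vb)
}
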