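#' Gaussian entropy of a region's partial-correlation submatrix
#'
#' \eqn{H = -\tfrac{1}{2}\,\ln\det(P_{N_1})} where \eqn{P_{N_1}} is the
#' partial-correlation matrix restricted to the region's nodes. H is zero
#' iff the submatrix is the identity (no within-region association) and
#' grows with the total amount of association; it is expressed in nats.
#'
#' @param pmat a \code{pcor_network} or a square symmetric matrix with
#'   unit diagonal.
#' @param nodes integer vector of node indices.
#' @param use_correlations if TRUE and \code{pmat} is a network estimated
#'   from data, the marginal correlation submatrix is used instead of the
#'   partial-correlation submatrix (off by default).
#' @return entropy in nats (>= 0 for a valid submatrix).
#' @examples
#' p <- diag(2); p[1, 2] <- p[2, 1] <- 0.5
#' gaussian_entropy(p, 1:2)   # -0.5 * log(0.75)
#' @export
gaussian_entropy <- function(pmat, nodes, use_correlations = FALSE) {
  m <- macro_matrix(pmat, use_correlations)
  sub <- m[nodes, nodes, drop = FALSE]
  ld <- determinant(sub, logarithm = TRUE)
  if (ld$sign <= 0)
    stop("validity error: submatrix is not positive definite")
  ev <- min(eigen(sub, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("validity error: submatrix is not positive definite")
  -0.5 * as.numeric(ld$modulus)
}

#' Mutual information between two node sets
#'
#' \eqn{MI = \tfrac{1}{2}\,\ln(\det P_{N_1}\,\det P_{N_2} /
#' \det P_{N_1 \cup N_2})}, in nats; zero iff the two blocks are
#' uncoupled in the (partial-)correlation structure, and non-negative for
#' positive-definite matrices by the Hadamard-Fischer inequality.
#'
#' @param pmat as in \code{\link{gaussian_entropy}}.
#' @param n1,n2 disjoint node sets.
#' @param use_correlations see \code{\link{gaussian_entropy}}.
#' @return mutual information in nats.
#' @export
mutual_information <- function(pmat, n1, n2, use_correlations = FALSE) {
  if (length(intersect(n1, n2)) > 0)
    stop("argument error: node sets must be disjoint")
  m <- macro_matrix(pmat, use_correlations)
  ld <- function(nodes) {
    sub <- m[nodes, nodes, drop = FALSE]
    d <- determinant(sub, logarithm = TRUE)
    ev <- min(eigen(sub, symmetric = TRUE, only.values = TRUE)$values)
    if (d$sign <= 0 || ev <= 0)
      stop("validity error: submatrix is not positive definite")
    as.numeric(d$modulus)
  }
  0.5 * (ld(n1) + ld(n2) - ld(c(n1, n2)))
}

macro_matrix <- function(pmat, use_correlations = FALSE) {
  if (inherits(pmat, "pcor_network")) {
    if (use_correlations) {
      if (is.null(pmat$cor)) stop("network carries no correlation matrix")
      pmat$cor
    } else pmat$pmat
  } else {
    as.matrix(pmat)
  }
}

#' Rank association values into weak / medium / strong levels
#'
#' One-dimensional k-means with k = 3 (50 restarts, deterministic under
#' the seed), with the clusters relabeled by ascending centroid.
#'
#' @param values numeric vector (>= 3 distinct values).
#' @param seed integer seed.
#' @return factor with levels weak < medium < strong, one per value.
#' @examples
#' rank_levels(c(0.1, 0.12, 0.5, 0.52, 0.9, 0.92))
#' @export
rank_levels <- function(values, seed = 1L) {
  if (length(unique(values)) < 3)
    stop("degenerate clustering: need at least 3 distinct values")
  km <- with_seed(seed, stats::kmeans(values, centers = 3, nstart = 50))
  ord <- order(km$centers)
  lab <- c("weak", "medium", "strong")[match(km$cluster, ord)]
  factor(lab, levels = c("weak", "medium", "strong"))
}

#' Lobe-level macro-network (integration/segregation summary)
#'
#' Collapses a 78-node partial-correlation network onto the ten
#' lobe-hemisphere clusters: per-cluster Gaussian entropy (within-region
#' association) and per-cluster-pair mutual information (between-region
#' association), each ranked weak/medium/strong by 1-D k-means. When two
#' networks are supplied the k-means ranking is fitted on the pooled
#' values of both groups (separately for H and MI) so the levels are
#' comparable across groups.
#'
#' @param networks a \code{pcor_network} or a named list of them
#'   (e.g. \code{list(control = ..., AD = ...)}).
#' @param atlas atlas defining the lobe clusters (default: the first
#'   network's atlas).
#' @param called optional \code{edge_set} (or list matching
#'   \code{networks}) used to flag significance: a region/pair is
#'   significant when it contains at least one called edge.
#' @param seed seed for the k-means ranking.
#' @param use_correlations see \code{\link{gaussian_entropy}}.
#' @return object of class \code{macro_network}: list with per-group
#'   data.frames \code{intra} (region, H, level, significant) and
#'   \code{inter} (region pair, MI, level, significant).
#' @export
build_macro_network <- function(networks, atlas = NULL, called = NULL,
                                seed = 1L, use_correlations = FALSE) {
  single <- inherits(networks, "pcor_network")
  if (single) networks <- list(network = networks)
  if (is.null(atlas)) atlas <- networks[[1]]$atlas
  if (is.null(atlas)) stop("an atlas is required")
  clusters <- lobe_clusters(atlas)
  regions <- names(clusters)
  pairs <- utils::combn(regions, 2)
  if (!is.null(called) && inherits(called, "edge_set"))
    called <- stats::setNames(rep(list(called), length(networks)),
                              names(networks))

  intra <- list(); inter <- list()
  for (g in names(networks)) {
    net <- networks[[g]]
    h <- vapply(regions, function(r)
      gaussian_entropy(net, clusters[[r]], use_correlations), numeric(1))
    mi <- vapply(seq_len(ncol(pairs)), function(p)
      mutual_information(net, clusters[[pairs[1, p]]],
                         clusters[[pairs[2, p]]], use_correlations),
      numeric(1))
    intra[[g]] <- data.frame(group = g, region = regions, H = h,
                             stringsAsFactors = FALSE)
    inter[[g]] <- data.frame(group = g, region_a = pairs[1, ],
                             region_b = pairs[2, ], MI = mi,
                             stringsAsFactors = FALSE)
    if (!is.null(called)) {
      es <- called[[g]]$edges
      in_region <- function(nodes)
        any(es$i %in% nodes & es$j %in% nodes)
      across <- function(na, nb)
        any((es$i %in% na & es$j %in% nb) | (es$i %in% nb & es$j %in% na))
      intra[[g]]$significant <- vapply(regions, function(r)
        in_region(clusters[[r]]), logical(1))
      inter[[g]]$significant <- vapply(seq_len(ncol(pairs)), function(p)
        across(clusters[[pairs[1, p]]], clusters[[pairs[2, p]]]),
        logical(1))
    }
  }
  intra <- do.call(rbind, intra)
  inter <- do.call(rbind, inter)
  # pooled ranking per quantity so groups share one scale; fewer than 3
  # distinct values (e.g. an exactly null model) degrades to "weak"
  rank_or_weak <- function(v) {
    if (length(unique(v)) < 3) {
      warning("degenerate clustering: fewer than 3 distinct values; ",
              "all levels set to 'weak'")
      factor(rep("weak", length(v)), levels = c("weak", "medium", "strong"))
    } else rank_levels(v, seed = seed)
  }
  intra$level <- rank_or_weak(intra$H)
  inter$level <- rank_or_weak(inter$MI)
  rownames(intra) <- rownames(inter) <- NULL
  structure(list(intra = intra, inter = inter, regions = regions),
            class = "macro_network")
}

#' @export
print.macro_network <- function(x, ...) {
  cat("macro-network:", length(x$regions), "lobe-hemisphere regions\n")
  cat("intra-region entropy levels:\n")
  print(table(x$intra$group, x$intra$level))
  cat("inter-region MI levels:\n")
  print(table(x$inter$group, x$inter$level))
  invisible(x)
}

#' Write a macro-network as JSON and node/edge TSV
#'
#' @param mn a \code{macro_network}.
#' @param json_path JSON output path (NULL to skip).
#' @param nodes_path,edges_path optional TSV paths for plotting tables.
#' @export
write_macro_network <- function(mn, json_path = NULL, nodes_path = NULL,
                                edges_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(regions = mn$regions, intra = mn$intra,
                              inter = mn$inter),
                         json_path, dataframe = "rows", pretty = TRUE,
                         auto_unbox = TRUE)
  if (!is.null(nodes_path))
    utils::write.table(mn$intra, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(edges_path))
    utils::write.table(mn$inter, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(json_path)
}
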