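#' Positive-predictive-value simulation for lfdr edge calling
#'
#' Monte-Carlo check of the edge-calling rule: replicate datasets are
#' drawn from sparse Gaussian graphical models, the shrinkage
#' partial-correlation network is estimated, the lfdr mixture is fitted,
#' and edges with lfdr below the threshold are called; the positive
#' predictive value of a replicate is the fraction of called edges that
#' are planted in the generating model. Replicates in which no edge is
#' called carry an undefined (NA) PPV.
#'
#' @param n_replicates number of simulated datasets.
#' @param n subjects per dataset.
#' @param n_edges planted edges.
#' @param partial_corr_range implied partial-correlation magnitudes.
#' @param threshold lfdr call threshold (default 0.2).
#' @param seed integer master seed.
#' @return list with \code{per_replicate} (data.frame: called, true
#'   positives, ppv), \code{mean_ppv} (mean over replicates with calls; 0
#'   when nothing is ever called), \code{total_called},
#'   \code{total_true_positive}.
#' @export
ppv_simulation <- function(n_replicates = 50, n = 15, n_edges = 100,
                           partial_corr_range = c(0.3, 0.5),
                           threshold = 0.2, seed = 1L) {
  atlas <- default_atlas()
  rows <- lapply(seq_len(n_replicates), function(r) {
    model <- build_precision(atlas, n_edges = n_edges,
                             partial_corr_range = partial_corr_range,
                             seed = child_seed(seed, 2 * r))
    data <- simulate_cohort(model, n, seed = child_seed(seed, 2 * r + 1))
    net <- estimate_network(data, adjust = FALSE)
    es <- call_edges(net, threshold = threshold)
    keys_true <- edge_pair_keys(model$true_edges, atlas$n_nodes)
    keys_called <- if (nrow(es$edges) > 0)
      edge_pair_keys(cbind(es$edges$i, es$edges$j), atlas$n_nodes)
    else integer(0)
    tp <- sum(keys_called %in% keys_true)
    data.frame(replicate = r, called = length(keys_called), tp = tp,
               ppv = if (length(keys_called) > 0)
                 tp / length(keys_called) else NA_real_)
  })
  per <- do.call(rbind, rows)
  defined <- per$ppv[!is.na(per$ppv)]
  list(per_replicate = per,
       mean_ppv = if (length(defined) > 0) mean(defined) else 0,
       total_called = sum(per$called),
       total_true_positive = sum(per$tp))
}

edge_pair_keys <- function(edges, k) {
  if (is.null(edges) || nrow(edges) == 0) return(integer(0))
  (pmin(edges[, 1], edges[, 2]) - 1) * k + pmax(edges[, 1], edges[, 2])
}
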