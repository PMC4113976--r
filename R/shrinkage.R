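#' Shrinkage covariance estimate with a heteroscedastic diagonal target
#'
#' Computes the analytic minimum-MSE shrinkage covariance of Schafer and
#' Strimmer: empirical correlations are shrunk toward zero (equivalently,
#' the covariance is shrunk toward its own diagonal, the covariance of a
#' graphical model of isolated nodes) while the empirical variances are
#' kept. The shrinkage intensity is the closed-form estimate
#' \deqn{\lambda = \sum_{i \ne j} \widehat{Var}(r_{ij}) / \sum_{i \ne j} r_{ij}^2,}
#' clipped to [0, 1]. For any \eqn{\lambda > 0} the result is
#' positive definite even when the number of variables exceeds the number
#' of samples, which is what makes partial-correlation estimation possible
#' at n = 15, k = 78.
#'
#' @param x n x k data matrix (no missing values, n >= 3).
#' @param shrink_variances if TRUE, variances are additionally shrunk
#'   toward their median (off by default; the diagonal then no longer
#'   equals the empirical variances).
#' @return object of class \code{shrunken_cov}: list with \code{sigma}
#'   (k x k), \code{lambda}, \code{n}, \code{k}.
#' @examples
#' x <- matrix(rnorm(50 * 5), 50, 5)
#' sc <- shrink_covariance(x)
#' sc$lambda
#' all.equal(diag(sc$sigma), apply(x, 2, var), check.attributes = FALSE)
#' @export
shrink_covariance <- function(x, shrink_variances = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("insufficient samples: need n >= 3")
  if (anyNA(x)) stop("x must not contain missing values")
  v <- apply(x, 2, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)[1]
    nm <- if (!is.null(colnames(x))) colnames(x)[bad] else bad
    stop("degenerate variable (zero variance): ", nm)
  }

  xs <- scale(x, center = TRUE, scale = TRUE)   # standardized scores
  # r_ij = n/(n-1) * mean_k(w_kij), w_kij = xs_ki * xs_kj
  wbar <- crossprod(xs) / n
  r <- (n / (n - 1)) * wbar
  # Var_hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2
  w2sum <- crossprod(xs^2)                      # sum_k w_kij^2
  var_r <- (n / (n - 1)^3) * (w2sum - n * wbar^2)
  num <- sum(var_r[upper.tri(var_r)])
  den <- sum(r[upper.tri(r)]^2)
  lambda <- if (den <= 0) 1 else min(1, max(0, num / den))

  rs <- (1 - lambda) * r
  diag(rs) <- 1
  if (shrink_variances) {
    # shrink variances toward their median with the analogous intensity
    z <- sweep(x, 2, colMeans(x))^2
    wv <- colSums((z - matrix(colMeans(z), n, k, byrow = TRUE))^2) *
      n / (n - 1)^3
    target <- stats::median(v)
    den_v <- sum((v - target)^2)
    lambda_v <- if (den_v <= 0) 1 else min(1, max(0, sum(wv) / den_v))
    v <- lambda_v * target + (1 - lambda_v) * v
  }
  sd_ <- sqrt(v)
  sigma <- rs * tcrossprod(sd_)
  structure(list(sigma = sigma, lambda = lambda, n = n, k = k),
            class = "shrunken_cov")
}

#' @export
print.shrunken_cov <- function(x, ...) {
  cat(sprintf("shrunken covariance: n = %d, k = %d, lambda = %.4f\n",
              x$n, x$k, x$lambda))
  invisible(x)
}

#' Partial correlations from a (shrunken) covariance
#'
#' Inverts the covariance and rescales: with \eqn{\Omega = \Sigma^{-1}},
#' the partial correlation between variables i and j given all others is
#' \eqn{p_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}}. The
#' diagonal is set to 1 by convention.
#'
#' @param cov a \code{shrunken_cov}, or a plain positive-definite k x k
#'   covariance matrix.
#' @param atlas optional \code{swm_atlas} attached to the result.
#' @param group optional provenance label.
#' @return object of class \code{pcor_network}: list with \code{pmat}
#'   (k x k partial correlations), \code{lfdr} (NULL until filled by
#'   \code{\link{edge_lfdr}}), \code{n}, \code{lambda}, \code{atlas},
#'   \code{group}.
#' @examples
#' s <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3)
#' partial_correlations(s)$pmat
#' @export
partial_correlations <- function(cov, atlas = NULL, group = NULL) {
  if (inherits(cov, "shrunken_cov")) {
    sigma <- cov$sigma; n <- cov$n; lambda <- cov$lambda
  } else {
    sigma <- as.matrix(cov); n <- NA_integer_; lambda <- NA_real_
  }
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("conditioning error: covariance is numerically singular"))
  omega <- chol2inv(ch)
  d <- 1 / sqrt(diag(omega))
  pmat <- -omega * tcrossprod(d)
  diag(pmat) <- 1
  pmat <- (pmat + t(pmat)) / 2
  if (!is.null(atlas)) {
    colnames(pmat) <- rownames(pmat) <- atlas$rois$label
  }
  structure(list(pmat = pmat, lfdr = NULL, n = n, lambda = lambda,
                 atlas = atlas, group = group),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  k <- ncol(x$pmat)
  cat(sprintf("partial-correlation network: %d nodes", k))
  if (!is.na(x$lambda)) cat(sprintf(", lambda = %.4f", x$lambda))
  if (!is.null(x$group)) cat(", group =", x$group)
  cat("\n")
  if (!is.null(x$lfdr))
    cat(sprintf("edges with lfdr < 0.2: %d\n",
                sum(x$lfdr[upper.tri(x$lfdr)] < 0.2)))
  invisible(x)
}

#' Covariate-adjusted partial-correlation network
#'
#' Removes linear effects of age and gender by augmenting the ROI matrix
#' with the covariates before shrinkage (k + 2 variables), applying the
#' partial-correlation transform, and retaining only the ROI block. For
#' the default 78-ROI atlas this is the k = 80 construction.
#'
#' @param x n x k ROI matrix, or an \code{mtr_dataset} (in which case
#'   age/gender are taken from it).
#' @param age,gender per-subject covariates (ignored when \code{x} is an
#'   \code{mtr_dataset}).
#' @param atlas optional atlas attached to the result.
#' @param group optional provenance label.
#' @return \code{pcor_network} on the k ROI nodes.
#' @export
adjust_covariates <- function(x, age = NULL, gender = NULL, atlas = NULL,
                              group = NULL) {
  if (inherits(x, "mtr_dataset")) {
    age <- x$age; gender <- x$gender
    if (is.null(atlas)) atlas <- x$atlas
    if (is.null(group)) group <- unique(x$group)[1]
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(age) || is.null(gender))
    stop("age and gender are required")
  if (stats::var(age) <= 0) stop("degenerate variable: age is constant")
  if (stats::var(gender) <= 0) stop("degenerate variable: gender is constant")
  k <- ncol(x)
  aug <- cbind(x, age = age, gender = gender)
  sc <- shrink_covariance(aug)
  net <- partial_correlations(sc)
  pmat <- net$pmat[seq_len(k), seq_len(k), drop = FALSE]
  if (!is.null(atlas)) colnames(pmat) <- rownames(pmat) <- atlas$rois$label
  structure(list(pmat = pmat, lfdr = NULL, n = sc$n, lambda = sc$lambda,
                 atlas = atlas, group = group),
            class = "pcor_network")
}

#' Estimate a network from a dataset (shrinkage + lfdr)
#'
#' Convenience wrapper: covariate-adjusted shrinkage partial correlations
#' followed by mixture fitting and per-edge lfdr.
#'
#' @param dataset an \code{mtr_dataset}.
#' @param adjust adjust for age/gender (default TRUE).
#' @return \code{pcor_network} with the \code{lfdr} matrix filled in.
#' @export
estimate_network <- function(dataset, adjust = TRUE) {
  stopifnot(inherits(dataset, "mtr_dataset"))
  net <- if (adjust) {
    adjust_covariates(dataset)
  } else {
    partial_correlations(shrink_covariance(dataset$values),
                         atlas = dataset$atlas,
                         group = unique(dataset$group)[1])
  }
  vals <- upper_vals(net$pmat)
  if (max(vals) - min(vals) <= .Machine$double.eps) {
    # fully shrunk (lambda = 1) network: no callable structure
    k <- ncol(net$pmat)
    net$lfdr <- matrix(1, k, k, dimnames = dimnames(net$pmat))
    net$mixture <- NULL
    return(net)
  }
  fit <- fit_mixture(vals, null_family = "hotelling")
  net$lfdr <- edge_lfdr(fit, net$pmat)
  net$mixture <- fit
  net
}

#' Write a network as square and long-format TSV
#'
#' @param net a \code{pcor_network}.
#' @param matrix_path path for the square partial-correlation TSV.
#' @param edges_path optional path for the long-format edge table
#'   (node_i, node_j, partial_corr, lfdr, edge_class).
#' @export
write_network_tsv <- function(net, matrix_path, edges_path = NULL) {
  utils::write.table(round(net$pmat, 8), matrix_path, sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(edges_path)) {
    if (is.null(net$atlas)) stop("edge table requires an atlas")
    ec <- edge_classes(net$atlas)
    ec$partial_corr <- net$pmat[cbind(ec$i, ec$j)]
    ec$lfdr <- if (!is.null(net$lfdr)) net$lfdr[cbind(ec$i, ec$j)] else NA
    ec$node_i <- net$atlas$rois$label[ec$i]
    ec$node_j <- net$atlas$rois$label[ec$j]
    utils::write.table(
      ec[, c("node_i", "node_j", "partial_corr", "lfdr", "class")],
      edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}
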