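#' Two-component mixture fit for edge statistics
#'
#' Models the marginal distribution of edge statistics (partial
#' correlations or z-scores) as \eqn{f = \eta_0 f_0 + (1-\eta_0) f_a}:
#' a null component with known parametric form and an alternative of
#' unspecified shape. The null scale is fitted by truncated maximum
#' likelihood on the central part of the empirical distribution (where
#' nulls dominate), \eqn{\eta_0} by central matching, and the marginal
#' density \eqn{f} by a Grenander-type monotone density estimate on the
#' absolute values.
#'
#' For partial correlations the null family is the Hotelling density
#' \eqn{f_0(p;\kappa) \propto (1-p^2)^{(\kappa-3)/2}}, with \eqn{\kappa}
#' treated as a free parameter: shrinkage contracts the null spread, so
#' the effective degrees of freedom are not n - 1. For z-scores the null
#' is a centered Gaussian with fitted standard deviation.
#'
#' The marginal density is estimated on the null p-value scale: the
#' statistics are mapped to \eqn{u = P_0(|X| > |x|)} (uniform under the
#' null) and a Grenander (non-increasing) density \eqn{g} is fitted to the
#' u sample; the implied lfdr is \eqn{\eta_0 / g(u)}, automatically
#' monotone in the statistic magnitude.
#'
#' @param values numeric vector of edge statistics (>= 100 values).
#' @param null_family "hotelling" (statistics in (-1, 1)) or "gaussian".
#' @param window central quantile of |values| used for null fitting
#'   (default 0.75).
#' @return object of class \code{mixture_fit}: list with \code{eta0},
#'   \code{kappa} (Hotelling) or \code{sd0} (Gaussian), \code{family},
#'   \code{f0} and \code{f} (vectorized density functions), and the
#'   Grenander knots.
#' @export
fit_mixture <- function(values, null_family = c("hotelling", "gaussian"),
                        window = 0.75) {
  null_family <- match.arg(null_family)
  values <- as.numeric(values[is.finite(values)])
  if (length(values) < 100)
    stop("need at least 100 values to fit the mixture")
  if (max(values) - min(values) <= .Machine$double.eps)
    stop("degenerate distribution: all values identical")
  ax <- abs(values)
  x0 <- stats::quantile(ax, window, names = FALSE)
  if (x0 <= 0) x0 <- min(ax[ax > 0])
  central <- values[ax <= x0]
  n_w <- length(central)

  if (null_family == "hotelling") {
    if (any(ax >= 1)) stop("hotelling family requires |values| < 1")
    negll <- function(log_km2) {
      kappa <- 2 + exp(log_km2)
      a <- (kappa - 1) / 2
      -(sum(((kappa - 3) / 2) * log1p(-central^2)) -
          n_w * (lbeta(0.5, a) + stats::pbeta(x0^2, 0.5, a, log.p = TRUE)))
    }
    opt <- stats::optimize(negll, c(log(0.5), log(1e8)))
    kappa <- 2 + exp(opt$minimum)
    p0_central <- stats::pbeta(x0^2, 0.5, (kappa - 1) / 2)
    f0 <- function(p) {
      exp(((kappa - 3) / 2) * log1p(-pmin(p^2, 1 - 1e-15)) -
            lbeta(0.5, (kappa - 1) / 2))
    }
    pv <- function(x)
      pmax(stats::pbeta(pmin(x^2, 1), 0.5, (kappa - 1) / 2,
                        lower.tail = FALSE), 1e-15)
    scale_par <- list(kappa = kappa)
  } else {
    negll <- function(log_sd) {
      sd0 <- exp(log_sd)
      -(sum(stats::dnorm(central, 0, sd0, log = TRUE)) -
          n_w * log(2 * stats::pnorm(x0 / sd0) - 1))
    }
    rng <- stats::sd(values)
    opt <- stats::optimize(negll, log(c(rng * 1e-3, rng * 10 + 1e-12)))
    sd0 <- exp(opt$minimum)
    p0_central <- 2 * stats::pnorm(x0 / sd0) - 1
    f0 <- function(z) stats::dnorm(z, 0, sd0)
    pv <- function(x)
      pmax(2 * stats::pnorm(abs(x) / sd0, lower.tail = FALSE), 1e-15)
    scale_par <- list(sd0 = sd0)
  }

  eta0 <- min(1, max(0, (n_w / length(values)) / p0_central))
  gren <- grenander_density(pv(ax))
  # marginal density on the statistic scale implied by the p-value-scale
  # Grenander estimate: f(x) = g(pv(|x|)) * f0(x); kept at or above the
  # null mass so the lfdr caps at 1
  f <- function(v) {
    pmax(gren$dens(pv(abs(v))) * f0(v), eta0 * f0(v))
  }
  structure(
    c(list(eta0 = eta0, family = null_family, f0 = f0, f = f, pv = pv,
           grenander = gren, window = window, x0 = x0,
           n_values = length(values)),
      scale_par),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture fit (%s null): eta0 = %.4f", x$family, x$eta0))
  if (x$family == "hotelling") cat(sprintf(", kappa = %.1f", x$kappa))
  else cat(sprintf(", sd0 = %.4f", x$sd0))
  cat("\n")
  invisible(x)
}

#' Grenander estimator of a non-increasing density on [0, Inf)
#'
#' Left-derivative of the least concave majorant of the empirical CDF of
#' the absolute statistics; a step function with non-increasing steps.
#'
#' @param x non-negative sample.
#' @return list with \code{knots}, \code{slopes} and the step density
#'   function \code{dens}.
#' @keywords internal
grenander_density <- function(x) {
  x <- sort(x)
  n <- length(x)
  ux <- unique(x)
  cdf <- cumsum(tabulate(match(x, ux))) / n
  # least concave majorant of {(0,0)} U {(ux_i, cdf_i)} via a slope stack
  px <- c(0, ux); py <- c(0, cdf)
  kx <- px[1]; ky <- py[1]
  for (i in 2:length(px)) {
    kx <- c(kx, px[i]); ky <- c(ky, py[i])
    m <- length(kx)
    while (m >= 3) {
      s1 <- (ky[m - 1] - ky[m - 2]) / (kx[m - 1] - kx[m - 2])
      s2 <- (ky[m] - ky[m - 1]) / (kx[m] - kx[m - 1])
      if (s2 <= s1) break
      kx <- kx[-(m - 1)]; ky <- ky[-(m - 1)]
      m <- length(kx)
    }
  }
  slopes <- diff(ky) / diff(kx)
  knots <- kx
  dens <- function(v) {
    idx <- findInterval(v, knots, left.open = TRUE, all.inside = FALSE)
    idx[v <= 0] <- 1L
    out <- numeric(length(v))
    inside <- idx >= 1 & idx <= length(slopes)
    out[inside] <- slopes[idx[inside]]
    out[v > knots[length(knots)]] <- 0
    out
  }
  list(knots = knots, slopes = slopes, dens = dens)
}

#' Per-edge local false discovery rate
#'
#' Evaluates \eqn{lfdr(p) = \eta_0 f_0(p) / f(p)}, capped at 1, for every
#' off-diagonal entry, and enforces monotonicity (lfdr non-increasing in
#' the statistic magnitude) by a conservative suffix-maximum pass.
#'
#' @param fit a \code{mixture_fit}.
#' @param values square symmetric statistic matrix, or a numeric vector.
#' @return lfdr matrix (diagonal 1) aligned with the input, or a vector.
#' @export
edge_lfdr <- function(fit, values) {
  stopifnot(inherits(fit, "mixture_fit"))
  is_mat <- is.matrix(values)
  v <- if (is_mat) upper_vals(values) else as.numeric(values)
  # eta0 * f0 / f reduces to eta0 / g(u) on the null p-value scale, which
  # stays well defined even where f0 underflows
  g <- fit$grenander$dens(fit$pv(abs(v)))
  if (any(!is.finite(g) | g <= 0))
    stop("density-support error: marginal density is zero at a value")
  lf <- pmin(1, fit$eta0 / g)
  # monotone envelope: largest lfdr at the smallest |statistic|
  o <- order(abs(v))
  lf_sorted <- lf[o]
  lf_mono <- rev(cummax(rev(lf_sorted)))
  lf[o] <- lf_mono
  if (!is_mat) return(lf)
  out <- sym_from_upper(lf, ncol(values), diag_val = 1)
  dimnames(out) <- dimnames(values)
  out
}

#' Call significant edges at an lfdr threshold
#'
#' @param network a \code{pcor_network} with its \code{lfdr} matrix filled
#'   (see \code{\link{estimate_network}}).
#' @param threshold lfdr cutoff (default 0.2, the conventional cutoff for
#'   highly significant edges with positive predictive value > 0.9).
#' @return object of class \code{edge_set}: list with \code{edges}
#'   (data.frame: i, j, statistic, lfdr, sign, class), \code{threshold},
#'   \code{kind = "single-group"}, and \code{disconnected} (named counts of
#'   edge-free nodes per hemisphere, when an atlas is attached).
#' @export
call_edges <- function(network, threshold = 0.2) {
  stopifnot(inherits(network, "pcor_network"))
  if (is.null(network$lfdr))
    stop("network has no lfdr matrix; run estimate_network() or edge_lfdr()")
  k <- ncol(network$pmat)
  iu <- which(upper.tri(network$pmat), arr.ind = TRUE)
  lf <- network$lfdr[iu]
  keep <- lf < threshold
  edges <- data.frame(
    i = iu[keep, 1], j = iu[keep, 2],
    statistic = network$pmat[iu[keep, , drop = FALSE]],
    lfdr = lf[keep]
  )
  edges$sign <- ifelse(edges$statistic >= 0, "positive", "negative")
  disconnected <- NULL
  if (!is.null(network$atlas)) {
    edges$class <- if (nrow(edges) > 0)
      classify_edge(network$atlas, edges$i, edges$j) else character(0)
    connected <- unique(c(edges$i, edges$j))
    iso <- setdiff(seq_len(k), connected)
    disconnected <- c(
      L = sum(network$atlas$rois$hemisphere[iso] == "L"),
      R = sum(network$atlas$rois$hemisphere[iso] == "R")
    )
  }
  structure(
    list(edges = edges, threshold = threshold, kind = "single-group",
         n_nodes = k, disconnected = disconnected, group = network$group),
    class = "edge_set"
  )
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge set (%s): %d edges at lfdr < %g\n",
              x$kind, nrow(x$edges), x$threshold))
  if (!is.null(x$edges$class) && nrow(x$edges) > 0)
    print(table(x$edges$class))
  if (!is.null(x$disconnected))
    cat(sprintf("disconnected nodes: %d (L: %d, R: %d)\n",
                sum(x$disconnected), x$disconnected["L"],
                x$disconnected["R"]))
  invisible(x)
}

#' Differential edges between two groups (Fisher-z / lfdr)
#'
#' Applies the Fisher transformation to the two partial-correlation
#' matrices, forms per-edge z-scores
#' \eqn{z = (\mathrm{atanh}\,p_a - \mathrm{atanh}\,p_b)/SE} with
#' \eqn{SE = \sqrt{1/(n_a-3) + 1/(n_b-3)}}, fits a Gaussian-null mixture to
#' the z-scores, and returns the edges with lfdr below the threshold. The
#' Gaussianity of the z-scores is summarized by a Jarque-Bera p-value.
#'
#' @param net_a,net_b \code{pcor_network}s on the same atlas/node order.
#' @param n_a,n_b group sample sizes (defaults taken from the networks).
#' @param threshold lfdr cutoff (default 0.2).
#' @return \code{edge_set} of kind "group-difference"; each edge carries
#'   both statistics, the z-score and a \code{direction} label (by
#'   partial-correlation magnitude, independent of sign); the Jarque-Bera
#'   p-value is in \code{$jarque_bera_p} and the mixture in \code{$mixture}.
#' @export
compare_groups <- function(net_a, net_b, n_a = net_a$n, n_b = net_b$n,
                           threshold = 0.2) {
  stopifnot(inherits(net_a, "pcor_network"), inherits(net_b, "pcor_network"))
  if (!identical(dim(net_a$pmat), dim(net_b$pmat)))
    stop("incompatible networks: different node counts")
  if (!is.null(net_a$atlas) && !is.null(net_b$atlas) &&
      !identical(net_a$atlas$rois$label, net_b$atlas$rois$label))
    stop("incompatible networks: different atlases")
  if (is.na(n_a) || is.na(n_b)) stop("sample sizes n_a, n_b are required")
  if (n_a <= 3 || n_b <= 3) stop("need n > 3 in both groups")
  se <- sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  iu <- which(upper.tri(net_a$pmat), arr.ind = TRUE)
  pa <- net_a$pmat[iu]; pb <- net_b$pmat[iu]
  z <- (atanh(pa) - atanh(pb)) / se
  jb <- jarque_bera(z)

  if (max(z) - min(z) <= .Machine$double.eps) {
    edges <- data.frame(i = integer(0), j = integer(0),
                        statistic = numeric(0), lfdr = numeric(0))
    fit <- NULL
  } else {
    fit <- fit_mixture(z, null_family = "gaussian")
    lf <- edge_lfdr(fit, z)
    keep <- lf < threshold
    edges <- data.frame(
      i = iu[keep, 1], j = iu[keep, 2],
      statistic = z[keep], lfdr = lf[keep],
      pcor_a = pa[keep], pcor_b = pb[keep]
    )
  }
  ga <- if (!is.null(net_a$group)) net_a$group else "a"
  gb <- if (!is.null(net_b$group)) net_b$group else "b"
  if (nrow(edges) > 0) {
    edges$direction <- ifelse(abs(edges$pcor_a) < abs(edges$pcor_b),
                              paste0(ga, "<", gb), paste0(ga, ">", gb))
    edges$sign <- ifelse(edges$statistic >= 0, "positive", "negative")
    if (!is.null(net_a$atlas))
      edges$class <- classify_edge(net_a$atlas, edges$i, edges$j)
  }
  zmat <- sym_from_upper(z, ncol(net_a$pmat), diag_val = 0)
  dimnames(zmat) <- dimnames(net_a$pmat)
  structure(
    list(edges = edges, threshold = threshold, kind = "group-difference",
         n_nodes = ncol(net_a$pmat), zmat = zmat,
         jarque_bera_p = jb$p.value,
         mixture = fit, groups = c(ga, gb),
         directions = c(paste0(ga, "<", gb), paste0(ga, ">", gb))),
    class = "edge_set"
  )
}

#' Hemispheric asymmetry of edges (Fisher-z / lfdr)
#'
#' Compares every left-intrahemispheric edge with its homotopic
#' right-hemisphere counterpart through the Fisher-z construction
#' \eqn{z = (\mathrm{atanh}\,p_{LH} - \mathrm{atanh}\,p_{RH})/\sqrt{2/(n-3)}},
#' followed by the same Gaussian-null lfdr machinery as the group
#' contrast (the signed construction keeps the null z-scores Gaussian,
#' which the Jarque-Bera summary verifies; direction labels are assigned
#' by partial-correlation magnitude, independently of sign). The two
#' samples come from the same subjects; the independent-samples standard
#' error is used by convention.
#'
#' @param net a \code{pcor_network} with an atlas providing homotopic
#'   pairing.
#' @param atlas atlas (defaults to the network's).
#' @param n sample size (defaults to the network's).
#' @param threshold lfdr cutoff (default 0.2).
#' @return \code{edge_set} of kind "hemisphere-difference"; rows carry the
#'   left-hemisphere node pair (i, j), the homotopic right pair
#'   (rh_i, rh_j), both magnitudes, z, lfdr, and a direction label
#'   "LH>RH" / "LH<RH".
#' @export
compare_hemispheres <- function(net, atlas = net$atlas, n = net$n,
                                threshold = 0.2) {
  stopifnot(inherits(net, "pcor_network"))
  if (is.null(atlas)) stop("atlas error: homotopic mapping required")
  validate_atlas(atlas)
  if (is.na(n) || n <= 3) stop("need n > 3")
  hp <- atlas$homotopic_pairs
  nl <- nrow(hp)
  lh <- which(upper.tri(matrix(0, nl, nl)), arr.ind = TRUE)
  li <- hp[lh[, 1], 1]; lj <- hp[lh[, 2], 1]
  ri <- hp[lh[, 1], 2]; rj <- hp[lh[, 2], 2]
  p_l <- net$pmat[cbind(li, lj)]
  p_r <- net$pmat[cbind(ri, rj)]
  se <- sqrt(2 / (n - 3))
  z <- (atanh(p_l) - atanh(p_r)) / se
  jb <- jarque_bera(z)
  if (max(z) - min(z) <= .Machine$double.eps) {
    fit <- NULL
    keep <- rep(FALSE, length(z))
    lf <- rep(1, length(z))
  } else {
    fit <- fit_mixture(z, null_family = "gaussian")
    lf <- edge_lfdr(fit, z)
    keep <- lf < threshold
  }
  edges <- data.frame(
    i = li[keep], j = lj[keep], rh_i = ri[keep], rh_j = rj[keep],
    statistic = z[keep], lfdr = lf[keep],
    pcor_lh = p_l[keep], pcor_rh = p_r[keep]
  )
  if (nrow(edges) > 0)
    edges$direction <- ifelse(abs(edges$pcor_lh) > abs(edges$pcor_rh),
                              "LH>RH", "LH<RH")
  structure(
    list(edges = edges, threshold = threshold,
         kind = "hemisphere-difference", n_nodes = ncol(net$pmat),
         z = z, lh_pairs = cbind(i = li, j = lj),
         jarque_bera_p = jb$p.value, mixture = fit, group = net$group,
         directions = c("LH>RH", "LH<RH")),
    class = "edge_set"
  )
}

#' Jarque-Bera normality test
#'
#' Moment-based test: \eqn{JB = n/6\,(S^2 + (K-3)^2/4)} compared to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric sample.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) return(list(statistic = NA_real_, p.value = NA_real_))
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(list(statistic = NA_real_, p.value = NA_real_))
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = jb, p.value = stats::pchisq(jb, 2, lower.tail = FALSE))
}

#' Write an edge set as TSV
#'
#' @param es an \code{edge_set}.
#' @param path output path.
#' @param atlas optional atlas for node labels.
#' @export
write_edge_set_tsv <- function(es, path, atlas = NULL) {
  edges <- es$edges
  if (!is.null(atlas) && nrow(edges) > 0) {
    edges$node_i <- atlas$rois$label[edges$i]
    edges$node_j <- atlas$rois$label[edges$j]
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
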