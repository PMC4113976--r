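#' Magnetization transfer ratio with noise mask
#'
#' MTR = 100 * (M0 - MS) / M0, the percentage loss of signal intensity
#' attributable to the magnetization transfer effect. Voxels with
#' MTR <= 10\% are flagged as excluded (noise mask); only included voxels
#' enter regional averages.
#'
#' @param m0 signal intensities without saturation (> 0).
#' @param ms signal intensities with saturation (same shape as m0).
#' @param mask_threshold exclusion threshold in percent (default 10).
#' @return data.frame with columns \code{mtr} (percent) and
#'   \code{included} (logical mask).
#' @examples
#' compute_mtr(c(100, 100, 50), c(60, 100, 0))
#' @export
compute_mtr <- function(m0, ms, mask_threshold = 10) {
  if (length(m0) != length(ms))
    stop("m0 and ms must have the same length")
  if (any(!is.finite(m0)) || any(m0 <= 0))
    stop("invalid intensity: m0 must be positive everywhere")
  mtr <- 100 * (m0 - ms) / m0
  data.frame(mtr = mtr, included = mtr > mask_threshold)
}

#' Mean MTR per ROI over mask-passing voxels
#'
#' @param mtr data.frame from \code{\link{compute_mtr}}, or a numeric
#'   vector of MTR values (in which case all voxels are treated as
#'   included unless \code{included} is given).
#' @param labels per-voxel ROI assignment (factor or character).
#' @param included optional logical mask.
#' @return named numeric vector of per-ROI means over included voxels.
#' @export
roi_mean <- function(mtr, labels, included = NULL) {
  if (is.data.frame(mtr)) {
    included <- mtr$included
    mtr <- mtr$mtr
  }
  if (is.null(included)) included <- rep(TRUE, length(mtr))
  if (length(labels) != length(mtr))
    stop("labels must have one entry per voxel")
  labels <- as.character(labels)
  rois <- unique(labels)
  empty <- rois[!rois %in% unique(labels[included])]
  if (length(empty) > 0)
    stop("missing region: no included voxels in ROI ",
         paste(empty, collapse = ", "))
  out <- tapply(mtr[included], labels[included], mean)
  out[rois]
}

#' Laterality score
#'
#' (L - R) / (L + R) for a homotopic pair of regional values; positive
#' scores indicate leftward asymmetry.
#'
#' @param left,right MTR values of the left and right members of a
#'   homotopic pair (vectorized).
#' @return score in (-1, 1).
#' @examples
#' laterality_score(30, 20)   # 0.2
#' @export
laterality_score <- function(left, right) {
  s <- left + right
  if (any(!is.finite(s)) || any(s <= 0))
    stop("undefined score: left + right must be positive")
  (left - right) / s
}

#' Per-subject laterality scores for all homotopic pairs
#'
#' @param dataset an \code{mtr_dataset}.
#' @return n x 39 matrix of laterality scores, columns named by area.
#' @export
laterality_scores <- function(dataset) {
  stopifnot(inherits(dataset, "mtr_dataset"))
  hp <- dataset$atlas$homotopic_pairs
  l <- dataset$values[, hp[, 1], drop = FALSE]
  r <- dataset$values[, hp[, 2], drop = FALSE]
  s <- (l - r) / (l + r)
  colnames(s) <- dataset$atlas$rois$area[hp[, 1]]
  s
}

#' Permutation GLM for laterality contrasts with step-up FDR
#'
#' Fits, per homotopic pair, a general linear model of the laterality
#' scores with age and gender as nuisance covariates, and estimates the
#' permutation distribution of the t-statistic:
#' \itemize{
#'   \item \code{contrast = "between"}: two-sample contrast of the group
#'     effect; inference by Freedman-Lane style permutation of group
#'     labels after residualizing on the nuisance covariates.
#'   \item \code{contrast = "within"}: one-sample contrast (mean score
#'     against zero) within one group; inference by random sign flips of
#'     the covariate-adjusted scores.
#' }
#' Two-sided p-values use the (1 + #exceedances)/(1 + n_perm) estimator;
#' q-values are Benjamini-Hochberg step-up across the pairs.
#'
#' @param scores n x m matrix of laterality scores (subjects x pairs).
#' @param group per-subject group labels (two levels for "between").
#' @param age,gender nuisance covariates.
#' @param contrast "between" or "within".
#' @param adjust for \code{contrast = "within"}: test covariate-adjusted
#'   scores (default TRUE) or raw scores.
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed.
#' @return object of class \code{laterality_result}: data.frame with one
#'   row per pair (score summaries, t, p, q, significant flag at
#'   FDR-corrected p < 0.05, degenerate flag), plus attributes.
#' @export
laterality_glm <- function(scores, group = NULL, age, gender,
                           contrast = c("between", "within"),
                           adjust = TRUE, n_perm = 10000, seed = 1L) {
  contrast <- match.arg(contrast)
  scores <- as.matrix(scores)
  n <- nrow(scores); m <- ncol(scores)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (length(age) != n || length(gender) != n)
    stop("covariates must have one entry per subject")

  z <- cbind(intercept = 1, age = as.numeric(age),
             gender = as.numeric(gender))
  qr_z <- qr(z)
  resid_z <- function(y) as.matrix(qr.resid(qr_z, y))

  if (contrast == "between") {
    if (is.null(group)) stop("group labels required for a between contrast")
    lv <- unique(as.character(group))
    if (length(lv) != 2) stop("between contrast requires exactly two groups")
    g <- as.numeric(as.character(group) == lv[2])
    yr <- resid_z(scores)
    xr <- as.numeric(resid_z(matrix(g, ncol = 1)))
    df <- n - ncol(z) - 1
    t_obs <- marginal_t(xr, yr, df)
    # Freedman-Lane: permute the nuisance-residualized scores and
    # re-residualize before computing the permuted t
    t_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        yp <- as.matrix(qr.resid(qr_z, yr[sample.int(n), , drop = FALSE]))
        marginal_t(xr, yp, df)
      }, numeric(m))
    })
  } else {
    y <- if (adjust) {
      # remove age/gender effects but keep the mean level being tested
      sweep(resid_z(scores), 2, colMeans(scores), "+")
    } else scores
    df <- n - 1
    t_obs <- one_sample_t(y)
    t_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        flips <- sample(c(-1, 1), n, replace = TRUE)
        yc <- sweep(y, 2, colMeans(y))       # exchangeable under the null
        one_sample_t(yc * flips)
      }, numeric(m))
    })
  }

  col_sd <- apply(scores, 2, stats::sd)
  t_obs[col_sd == 0] <- NaN
  degenerate <- !is.finite(t_obs)
  p <- vapply(seq_len(m), function(j) {
    if (degenerate[j]) return(1)
    tp <- t_perm[j, ]
    tp[!is.finite(tp)] <- 0
    (1 + sum(abs(tp) >= abs(t_obs[j]))) / (1 + n_perm)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")

  res <- data.frame(
    pair = if (!is.null(colnames(scores))) colnames(scores)
           else paste0("pair", seq_len(m)),
    mean_score = colMeans(scores),
    t = t_obs, p = p, q = q,
    significant = q < 0.05 & !degenerate,
    degenerate = degenerate
  )
  if (contrast == "between") {
    res$mean_a <- colMeans(scores[g == 0, , drop = FALSE])
    res$mean_b <- colMeans(scores[g == 1, , drop = FALSE])
  }
  structure(res, contrast = contrast, n_perm = n_perm,
            class = c("laterality_result", "data.frame"))
}

# t-statistics of a single regressor against each column of yr, both
# already residualized on the nuisance design (Freedman-Lane)
marginal_t <- function(xr, yr, df) {
  sxx <- sum(xr^2)
  if (sxx <= 0) return(rep(NaN, ncol(yr)))
  b <- as.numeric(crossprod(xr, yr)) / sxx
  rss <- colSums(yr^2) - b^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  out <- b / se
  out[se == 0] <- NaN
  out
}

one_sample_t <- function(y) {
  n <- nrow(y)
  mu <- colMeans(y)
  s <- sqrt(colSums(sweep(y, 2, mu)^2) / (n - 1))
  out <- mu / (s / sqrt(n))
  out[s == 0] <- NaN
  out
}

#' Laterality analysis of one or two datasets
#'
#' Convenience wrapper producing the within-group and (optionally)
#' between-group laterality tables for MTR datasets.
#'
#' @param dataset_a an \code{mtr_dataset}.
#' @param dataset_b optional second \code{mtr_dataset} for the
#'   between-group contrast.
#' @param n_perm permutations per contrast.
#' @param seed integer seed.
#' @return list of \code{laterality_result} tables: \code{within_a},
#'   optionally \code{within_b} and \code{between}.
#' @export
laterality_analysis <- function(dataset_a, dataset_b = NULL,
                                n_perm = 10000, seed = 1L) {
  sa <- laterality_scores(dataset_a)
  out <- list(
    within_a = laterality_glm(sa, age = dataset_a$age,
                              gender = dataset_a$gender,
                              contrast = "within", n_perm = n_perm,
                              seed = child_seed(seed, 1))
  )
  if (!is.null(dataset_b)) {
    sb <- laterality_scores(dataset_b)
    out$within_b <- laterality_glm(sb, age = dataset_b$age,
                                   gender = dataset_b$gender,
                                   contrast = "within", n_perm = n_perm,
                                   seed = child_seed(seed, 2))
    out$between <- laterality_glm(
      rbind(sa, sb),
      group = c(dataset_a$group, dataset_b$group),
      age = c(dataset_a$age, dataset_b$age),
      gender = c(dataset_a$gender, dataset_b$gender),
      contrast = "between", n_perm = n_perm, seed = child_seed(seed, 3))
  }
  out
}
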