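#' Build a sparse Gaussian graphical model over the atlas
#'
#' Constructs a precision matrix whose implied partial-correlation matrix
#' has magnitudes inside \code{partial_corr_range} exactly on a set of
#' randomly placed edges and is zero elsewhere. Edges are placed under a
#' per-node degree cap and magnitudes drawn uniformly from the range;
#' positive definiteness is then enforced by selective damping: while the
#' smallest eigenvalue of the unit-diagonal precision is below
#' \code{min_eig}, the edges most involved in the offending eigenvector
#' are shrunk (never below the range minimum). This preserves the drawn
#' magnitude distribution as far as the positive-definiteness geometry
#' allows.
#'
#' @param atlas an \code{swm_atlas} (defines k, the number of nodes).
#' @param n_edges number of nonzero off-diagonal pairs to plant.
#' @param partial_corr_range length-2 interval of admissible partial
#'   correlation magnitudes, strictly inside (0, 1).
#' @param seed integer seed.
#' @param sign_pos_prob probability that a planted edge is positive
#'   (default 0.9; structural covariance edges are predominantly positive).
#' @param min_eig lower bound imposed on the smallest eigenvalue of the
#'   unit-diagonal precision matrix (default 0.1).
#' @param regional_means per-ROI mean MTR in percent; a single range
#'   c(lo, hi) draws one mean per area and copies it to both hemispheres.
#'   Default c(30, 60).
#' @param noise_sd per-ROI marginal standard deviation of MTR in percent
#'   (recycled; default 2).
#' @param max_retries placement retries before giving up.
#' @return object of class \code{precision_model}: list with \code{omega}
#'   (unit-diagonal precision), \code{sigma} (model covariance on the MTR
#'   scale), \code{pcor_true} (implied partial correlations),
#'   \code{true_edges} (m x 2 matrix, i < j), \code{regional_means},
#'   \code{noise_sd}, \code{atlas}.
#' @examples
#' m <- build_precision(default_atlas(), n_edges = 20, seed = 1)
#' nrow(m$true_edges)
#' min(eigen(m$omega, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
build_precision <- function(atlas, n_edges,
                            partial_corr_range = c(0.3, 0.5),
                            seed = 1L,
                            sign_pos_prob = 0.9,
                            min_eig = 0.1,
                            regional_means = c(30, 60),
                            noise_sd = 2,
                            max_retries = 50L) {
  validate_atlas(atlas)
  k <- atlas$n_nodes
  lo <- partial_corr_range[1]; hi <- partial_corr_range[2]
  if (!(lo > 0 && hi < 1 && lo <= hi))
    stop("partial_corr_range must satisfy 0 < lo <= hi < 1")
  if (n_edges > k * (k - 1) / 2) stop("n_edges exceeds the number of pairs")
  deg_cap <- max(1L, floor((1 - min_eig) / lo))
  if (n_edges > 0 && 2 * n_edges > k * deg_cap)
    stop("model-construction error: requested edges incompatible with ",
         "positive definiteness under the magnitude range")

  with_seed(seed, {
    placed <- NULL
    for (trial in seq_len(max_retries)) {
      placed <- place_edges(k, n_edges, deg_cap)
      if (!is.null(placed)) break
    }
    if (is.null(placed) && n_edges > 0)
      stop("model-construction error: could not place edges after retries")
    if (n_edges == 0) placed <- matrix(integer(0), 0, 2)

    pcor <- matrix(0, k, k)
    ev_min <- 1
    if (n_edges > 0) {
      mag <- stats::runif(n_edges, lo, hi)
      sgn <- ifelse(stats::runif(n_edges) < sign_pos_prob, 1, -1)
      ok <- FALSE
      for (it in seq_len(1000L)) {
        pcor <- matrix(0, k, k)
        vals <- mag * sgn
        pcor[placed] <- vals
        pcor[placed[, c(2, 1), drop = FALSE]] <- vals
        e <- eigen(diag(k) - pcor, symmetric = TRUE)
        ev_min <- e$values[k]
        if (ev_min >= min_eig) { ok <- TRUE; break }
        # damp the edges most involved in the offending eigen-mode
        v <- e$vectors[, k]
        w <- abs(v[placed[, 1]] * v[placed[, 2]])
        sel <- w >= stats::quantile(w, 0.75)
        mag[sel] <- pmax(lo, mag[sel] * 0.93)
      }
      if (!ok)
        stop("model-construction error: requested edge weights incompatible ",
             "with positive definiteness")
    }
    omega <- diag(k) - pcor

    sigma0 <- chol2inv(chol(omega))
    if (length(regional_means) == 2 && is.null(names(regional_means))) {
      per_area <- stats::runif(k / 2, regional_means[1], regional_means[2])
      mu <- rep(per_area, 2)
    } else {
      mu <- rep_len(regional_means, k)
    }
    sds <- rep_len(noise_sd, k)
    s <- sds / sqrt(diag(sigma0))
    sigma <- sigma0 * tcrossprod(s)

    pc <- pcor
    diag(pc) <- 1
    structure(
      list(omega = omega, sigma = sigma, pcor_true = pc,
           true_edges = placed, regional_means = mu, noise_sd = sds,
           atlas = atlas, min_eig = ev_min),
      class = "precision_model"
    )
  })
}

# random edge placement under a per-node degree cap; NULL when stuck
place_edges <- function(k, n_edges, deg_cap) {
  deg <- integer(k)
  used <- matrix(FALSE, k, k)
  placed <- matrix(0L, n_edges, 2)
  got <- 0L
  attempts <- 0L
  max_attempts <- 200L * max(n_edges, 1L)
  while (got < n_edges && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(k, 2)
    i <- min(ij); j <- max(ij)
    if (used[i, j] || deg[i] >= deg_cap || deg[j] >= deg_cap) next
    got <- got + 1L
    placed[got, ] <- c(i, j)
    used[i, j] <- TRUE
    deg[i] <- deg[i] + 1L
    deg[j] <- deg[j] + 1L
  }
  if (got < n_edges) NULL else placed[order(placed[, 1], placed[, 2]), ,
                                       drop = FALSE]
}

#' @export
print.precision_model <- function(x, ...) {
  cat("Gaussian graphical model:", nrow(x$omega), "nodes,",
      nrow(x$true_edges), "true edges\n")
  if (nrow(x$true_edges) > 0) {
    mags <- abs(x$pcor_true[x$true_edges])
    cat(sprintf("partial-correlation magnitudes: %.3f-%.3f\n",
                min(mags), max(mags)))
  }
  cat(sprintf("smallest precision eigenvalue: %.4f\n", x$min_eig))
  invisible(x)
}

#' Simulate a cohort of subjects from a precision model
#'
#' Subject rows are independent multivariate-normal draws from the model
#' covariance, shifted by the regional means, optional linear age and
#' gender effects, and optional hemispheric-asymmetry offsets added to the
#' left member of homotopic pairs.
#'
#' @param model a \code{precision_model}.
#' @param n_subjects number of subjects (>= 2).
#' @param group group label attached to every subject (default "control").
#' @param covariate_effect optional list with per-ROI slope vectors
#'   \code{age} (MTR\% per year, centered at the mean age) and
#'   \code{gender} (MTR\% offset for gender code 1); recycled to k.
#' @param asymmetry optional numeric vector of length 39 (one offset per
#'   homotopic pair, added to the left node's mean) or a named subset such
#'   as \code{c("10" = 2)} using area labels.
#' @param age_range ages are drawn uniformly from this interval
#'   (default 55-80 years).
#' @param gender_prob probability of gender code 1 (default 0.5).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return object of class \code{mtr_dataset}: list with \code{values}
#'   (n x k matrix, ROI labels as colnames), \code{group}, \code{age},
#'   \code{gender}, \code{atlas}.
#' @export
simulate_cohort <- function(model, n_subjects, group = "control",
                            covariate_effect = NULL, asymmetry = NULL,
                            age_range = c(55, 80), gender_prob = 0.5,
                            seed = 1L) {
  stopifnot(inherits(model, "precision_model"))
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  ev <- min(eigen(model$sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("model covariance is not positive definite")
  atlas <- model$atlas
  k <- atlas$n_nodes

  mu <- model$regional_means
  if (!is.null(asymmetry)) {
    offs <- numeric(k / 2)
    if (!is.null(names(asymmetry))) {
      left_areas <- atlas$rois$area[atlas$homotopic_pairs[, 1]]
      idx <- match(names(asymmetry), left_areas)
      if (anyNA(idx)) stop("asymmetry names must be area labels")
      offs[idx] <- asymmetry
    } else {
      offs <- rep_len(asymmetry, k / 2)
    }
    mu[atlas$homotopic_pairs[, 1]] <- mu[atlas$homotopic_pairs[, 1]] + offs
  }

  with_seed(seed, {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    gender <- stats::rbinom(n_subjects, 1, gender_prob)
    z <- matrix(stats::rnorm(n_subjects * k), n_subjects, k)
    x <- z %*% chol(model$sigma)
    x <- sweep(x, 2, mu, "+")
    if (!is.null(covariate_effect)) {
      if (!is.null(covariate_effect$age)) {
        slope <- rep_len(covariate_effect$age, k)
        x <- x + outer(age - mean(age_range), slope)
      }
      if (!is.null(covariate_effect$gender)) {
        eff <- rep_len(covariate_effect$gender, k)
        x <- x + outer(gender, eff)
      }
    }
    colnames(x) <- atlas$rois$label
    mtr_dataset(x, group = rep(group, n_subjects), age = age,
                gender = gender, atlas = atlas)
  })
}

#' Construct and validate an MTR dataset
#'
#' @param values n x k numeric matrix of mean regional MTR values
#'   (percent), columns ordered and named as in the atlas.
#' @param group character vector of per-subject group labels.
#' @param age numeric per-subject age in years.
#' @param gender 0/1 per-subject gender code.
#' @param atlas an \code{swm_atlas}.
#' @return object of class \code{mtr_dataset}.
#' @export
mtr_dataset <- function(values, group, age, gender, atlas) {
  validate_atlas(atlas)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != atlas$n_nodes)
    stop("values must have one column per atlas node")
  if (anyNA(values)) stop("values must not contain missing entries")
  if (length(group) != n || length(age) != n || length(gender) != n)
    stop("covariates must have one entry per subject")
  structure(
    list(values = values, group = as.character(group),
         age = as.numeric(age), gender = as.integer(gender), atlas = atlas),
    class = "mtr_dataset"
  )
}

#' @export
print.mtr_dataset <- function(x, ...) {
  cat("MTR dataset:", nrow(x$values), "subjects x", ncol(x$values), "ROIs\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$group)),
                               table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a two-group scenario with lost and gained edges
#'
#' The first group is drawn from \code{base}; the second group from a
#' modified model in which \code{lost_edges} are removed from the precision
#' support and \code{gained_edges} are planted.
#'
#' @param base a \code{precision_model} (the control-group model).
#' @param lost_edges m x 2 matrix of node pairs to zero out; must be a
#'   subset of \code{base$true_edges}.
#' @param gained_edges m x 2 matrix of node pairs to plant; must be
#'   disjoint from \code{base$true_edges}.
#' @param gained_weights partial correlations for the gained edges
#'   (recycled; nonzero; default 0.4).
#' @param n_per_group subjects per group (default 15).
#' @param seed integer seed.
#' @param ... further arguments passed to \code{simulate_cohort} (e.g.
#'   covariate effects).
#' @return list with elements \code{control} and \code{ad} (both
#'   \code{mtr_dataset}), and \code{model_control}, \code{model_ad}.
#' @export
two_group_scenario <- function(base, lost_edges = NULL, gained_edges = NULL,
                               gained_weights = 0.4, n_per_group = 15,
                               seed = 1L, ...) {
  stopifnot(inherits(base, "precision_model"))
  lost_edges <- normalize_edges(lost_edges)
  gained_edges <- normalize_edges(gained_edges)
  base_keys <- edge_keys(base$true_edges, nrow(base$omega))
  if (nrow(lost_edges) > 0 &&
      !all(edge_keys(lost_edges, nrow(base$omega)) %in% base_keys))
    stop("lost_edges must be a subset of the base model's true edges")
  if (nrow(gained_edges) > 0 &&
      any(edge_keys(gained_edges, nrow(base$omega)) %in% base_keys))
    stop("gained_edges must be disjoint from the base model's true edges")
  if (any(rep_len(gained_weights, max(1, nrow(gained_edges))) == 0))
    stop("gained edges must have nonzero weight")

  pc <- base$pcor_true
  diag(pc) <- 0
  if (nrow(lost_edges) > 0)
    for (e in seq_len(nrow(lost_edges))) {
      i <- lost_edges[e, 1]; j <- lost_edges[e, 2]
      pc[i, j] <- pc[j, i] <- 0
    }
  if (nrow(gained_edges) > 0) {
    w <- rep_len(gained_weights, nrow(gained_edges))
    for (e in seq_len(nrow(gained_edges))) {
      i <- gained_edges[e, 1]; j <- gained_edges[e, 2]
      pc[i, j] <- pc[j, i] <- w[e]
    }
  }
  omega2 <- diag(nrow(pc)) - pc
  ev <- min(eigen(omega2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8)
    stop("model-construction error: modification breaks positive definiteness")

  model2 <- base
  model2$omega <- omega2
  sigma0 <- chol2inv(chol(omega2))
  s <- base$noise_sd / sqrt(diag(sigma0))
  model2$sigma <- sigma0 * tcrossprod(s)
  diag(pc) <- 1
  model2$pcor_true <- pc
  keep <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
  model2$true_edges <- unname(keep[order(keep[, 1], keep[, 2]), ,
                                   drop = FALSE])
  model2$min_eig <- ev

  ctrl <- simulate_cohort(base, n_per_group, group = "control",
                          seed = child_seed(seed, 1), ...)
  ad <- simulate_cohort(model2, n_per_group, group = "AD",
                        seed = child_seed(seed, 2), ...)
  list(control = ctrl, ad = ad, model_control = base, model_ad = model2)
}

normalize_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0)
    return(matrix(integer(0), 0, 2))
  edges <- matrix(as.integer(edges), ncol = 2)
  cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
}

edge_keys <- function(edges, k) {
  if (nrow(edges) == 0) return(integer(0))
  (pmin(edges[, 1], edges[, 2]) - 1) * k + pmax(edges[, 1], edges[, 2])
}

#' Write / read an MTR dataset as TSV
#'
#' Two files: a values table (header of ROI labels, one row per subject)
#' and a covariates table (subject, group, age, gender).
#'
#' @param dataset an \code{mtr_dataset}.
#' @param values_path,covariates_path file paths.
#' @param atlas atlas used to validate on read.
#' @return \code{read_mtr_dataset} returns the \code{mtr_dataset}.
#' @export
write_mtr_dataset <- function(dataset, values_path, covariates_path) {
  stopifnot(inherits(dataset, "mtr_dataset"))
  utils::write.table(dataset$values, values_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cov <- data.frame(subject = seq_len(nrow(dataset$values)),
                    group = dataset$group, age = dataset$age,
                    gender = dataset$gender)
  utils::write.table(cov, covariates_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(values_path)
}

#' @rdname write_mtr_dataset
#' @export
read_mtr_dataset <- function(values_path, covariates_path,
                             atlas = default_atlas()) {
  values <- as.matrix(utils::read.delim(values_path, check.names = FALSE))
  cov <- utils::read.delim(covariates_path)
  mtr_dataset(values, group = cov$group, age = cov$age,
              gender = cov$gender, atlas = atlas)
}
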