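#' Tally an edge set by sign and gross topology
#'
#' Produces the positive/negative x (intra-LH, intra-RH, interhemispheric)
#' count layout used to characterize inferred networks, together with the
#' marginal total.
#'
#' @param es an \code{edge_set} of kind "single-group" whose edges carry
#'   \code{sign} and \code{class}.
#' @return list with \code{counts} (2 x 3 matrix), \code{total},
#'   \code{disconnected}.
#' @export
edge_tally <- function(es) {
  stopifnot(inherits(es, "edge_set"))
  cls <- c("intra-LH", "intra-RH", "interhemispheric")
  sgn <- c("positive", "negative")
  counts <- matrix(0L, 2, 3, dimnames = list(sgn, cls))
  if (nrow(es$edges) > 0) {
    tab <- table(factor(es$edges$sign, sgn), factor(es$edges$class, cls))
    counts[] <- as.integer(tab)
  }
  list(counts = counts, total = sum(counts), disconnected = es$disconnected)
}

#' Tally a differential edge set by direction and gross topology
#'
#' @param es an \code{edge_set} of kind "group-difference" (direction x
#'   class layout) or "hemisphere-difference" (direction totals only).
#' @return list with \code{counts} and per-direction \code{totals}.
#' @export
diff_tally <- function(es) {
  stopifnot(inherits(es, "edge_set"))
  dirs <- es$directions
  if (es$kind == "group-difference") {
    cls <- c("intra-LH", "intra-RH", "interhemispheric")
    counts <- matrix(0L, length(dirs), 3, dimnames = list(dirs, cls))
    if (nrow(es$edges) > 0) {
      tab <- table(factor(es$edges$direction, dirs),
                   factor(es$edges$class, cls))
      counts[] <- as.integer(tab)
    }
    list(counts = counts, totals = rowSums(counts), total = sum(counts))
  } else {
    counts <- if (nrow(es$edges) > 0)
      table(factor(es$edges$direction, dirs))
    else stats::setNames(rep(0L, length(dirs)), dirs)
    counts <- stats::setNames(as.integer(counts), dirs)
    list(counts = counts, totals = counts, total = sum(counts))
  }
}

#' Default run configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_edges planted edges in the control-group model.
#' @param partial_corr_range implied partial-correlation magnitude range
#'   for the planted edges (default c(0.3, 0.5)).
#' @param n_lost,n_gained edges removed from / added to the second group's
#'   model.
#' @param n_per_group subjects per group.
#' @param lfdr_threshold edge-call cutoff (default 0.2).
#' @param lfdr_band density-integration band (default c(0.2, 0.5)).
#' @param laterality_n_perm permutations for the laterality GLM
#'   (default 10000).
#' @param topology_n_perm label shuffles for the topology permutation
#'   test; 0 skips the test (the default: each shuffle re-runs the whole
#'   estimation pipeline, so this stage is opt-in).
#' @param n_points density-grid size (default 30).
#' @param out optional output directory for artifacts.
#' @param values_a,covariates_a,values_b,covariates_b optional TSV paths;
#'   when given, data are loaded instead of simulated.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, n_edges = 100,
                       partial_corr_range = c(0.3, 0.5),
                       n_lost = 20, n_gained = 10,
                       n_per_group = 15, lfdr_threshold = 0.2,
                       lfdr_band = c(0.2, 0.5), laterality_n_perm = 10000,
                       topology_n_perm = 0, n_points = 30, out = NULL,
                       values_a = NULL, covariates_a = NULL,
                       values_b = NULL, covariates_b = NULL) {
  cfg <- list(seed = as.integer(seed), n_edges = n_edges,
              partial_corr_range = partial_corr_range, n_lost = n_lost,
              n_gained = n_gained, n_per_group = n_per_group,
              lfdr_threshold = lfdr_threshold, lfdr_band = lfdr_band,
              laterality_n_perm = laterality_n_perm,
              topology_n_perm = topology_n_perm, n_points = n_points,
              out = out, values_a = values_a, covariates_a = covariates_a,
              values_b = values_b, covariates_b = covariates_b)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (cfg$lfdr_threshold <= 0 || cfg$lfdr_threshold >= 1)
    stop("lfdr threshold must be in (0, 1)")
  if (any(cfg$lfdr_band <= 0) || any(cfg$lfdr_band >= 1) ||
      cfg$lfdr_band[1] >= cfg$lfdr_band[2])
    stop("lfdr band must be an increasing interval inside (0, 1)")
  if (cfg$lfdr_threshold > cfg$lfdr_band[2])
    stop("edge-call threshold must not exceed the band's upper bound")
  if (is.null(cfg$seed)) stop("a seed is mandatory")
  invisible(cfg)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path configuration file; YAML when the yaml package is
#'   available and the extension is .yml/.yaml, JSON otherwise.
#' @param ... overrides applied after loading.
#' @return \code{run_config}.
#' @export
read_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Sequences every stage: simulate (or load) the two cohorts, laterality
#' permutation GLM, covariate-adjusted shrinkage networks with lfdr,
#' significant-edge calling and tallies, group and hemisphere contrasts,
#' the lobe-level macro-network, and density-integrated topology (plus the
#' optional label-permutation group test). Identical configurations and
#' seeds give identical reports.
#'
#' @param config a \code{run_config} (or a path accepted by
#'   \code{\link{read_config}}).
#' @return object of class \code{study_report}.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  atlas <- default_atlas()

  data <- stage("data", {
    if (!is.null(config$values_a)) {
      a <- read_mtr_dataset(config$values_a, config$covariates_a, atlas)
      b <- if (!is.null(config$values_b))
        read_mtr_dataset(config$values_b, config$covariates_b, atlas)
      else NULL
      list(control = a, ad = b)
    } else {
      base <- build_precision(atlas, n_edges = config$n_edges,
                              partial_corr_range = config$partial_corr_range,
                              seed = child_seed(config$seed, 10))
      te <- base$true_edges
      lost <- te[seq_len(min(config$n_lost, nrow(te))), , drop = FALSE]
      free <- which(upper.tri(base$omega) & base$pcor_true == 0,
                    arr.ind = TRUE)
      # draw gained edges until the modified precision stays positive
      # definite (the base model sits near the feasibility boundary)
      sc <- NULL
      for (try in seq_len(50L)) {
        gained <- with_seed(child_seed(config$seed, 11 + 100 * try), {
          free[sample.int(nrow(free), config$n_gained), , drop = FALSE]
        })
        sc <- tryCatch(
          two_group_scenario(base, lost, gained,
                             n_per_group = config$n_per_group,
                             seed = child_seed(config$seed, 12)),
          error = function(e) NULL)
        if (!is.null(sc)) break
      }
      if (is.null(sc))
        stop("could not construct a positive-definite two-group scenario")
      sc[c("control", "ad")]
    }
  })

  laterality <- stage("laterality", {
    laterality_analysis(data$control, data$ad,
                        n_perm = config$laterality_n_perm,
                        seed = child_seed(config$seed, 20))
  })

  nets <- stage("networks", {
    lapply(data[!vapply(data, is.null, logical(1))], estimate_network)
  })

  called <- stage("edge_calls", {
    lapply(nets, call_edges, threshold = config$lfdr_threshold)
  })
  tallies <- lapply(called, edge_tally)

  contrasts <- stage("contrasts", {
    out <- list()
    if (length(nets) == 2) {
      out$group <- compare_groups(nets[[2]], nets[[1]],
                                  threshold = config$lfdr_threshold)
      out$group_tally <- diff_tally(out$group)
    }
    out$hemisphere <- lapply(nets, compare_hemispheres,
                             threshold = config$lfdr_threshold)
    out$hemisphere_tally <- lapply(out$hemisphere, diff_tally)
    out
  })

  macro <- stage("macro_network", {
    build_macro_network(nets, atlas = atlas, called = called,
                        seed = child_seed(config$seed, 30))
  })

  topology <- stage("topology", {
    reps <- lapply(nets, topology_report, lfdr_band = config$lfdr_band,
                   n_points = config$n_points)
    perm <- NULL
    if (config$topology_n_perm >= 100 && length(data) == 2 &&
        !is.null(data$ad)) {
      perm <- permutation_metric_test(
        data$control, data$ad, n_perm = config$topology_n_perm,
        lfdr_band = config$lfdr_band,
        n_points = min(config$n_points, 10),
        seed = child_seed(config$seed, 40))
    }
    list(reports = reps, permutation = perm)
  })

  report <- structure(
    list(config = unclass(config),
         shrinkage = lapply(nets, function(n)
           list(lambda = n$lambda,
                eta0 = if (is.null(n$mixture)) NA else n$mixture$eta0,
                kappa = if (is.null(n$mixture)) NA else n$mixture$kappa,
                edges_02 = sum(upper_vals(n$lfdr) < 0.2),
                edges_05 = sum(upper_vals(n$lfdr) < 0.5))),
         laterality = lapply(laterality, as.data.frame),
         edge_tallies = tallies,
         group_contrast = if (!is.null(contrasts$group))
           list(tally = contrasts$group_tally,
                jarque_bera_p = contrasts$group$jarque_bera_p,
                edges = contrasts$group$edges),
         hemisphere_contrast = lapply(
           names(contrasts$hemisphere), function(g)
             list(group = g,
                  tally = contrasts$hemisphere_tally[[g]],
                  jarque_bera_p = contrasts$hemisphere[[g]]$jarque_bera_p,
                  edges = contrasts$hemisphere[[g]]$edges)),
         macro = list(intra = macro$intra, inter = macro$inter),
         topology = list(
           integrated = lapply(topology$reports, `[[`, "integrated"),
           hubs = lapply(topology$reports, `[[`, "hub_labels"),
           curves = lapply(topology$reports, `[[`, "curves"),
           permutation = topology$permutation)),
    class = "study_report"
  )
  if (!is.null(config$out)) write_study_report(report, config$out)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report\n")
  for (g in names(x$edge_tallies)) {
    t <- x$edge_tallies[[g]]
    cat(sprintf("  %s: %d edges at lfdr < %g (disconnected: %d)\n", g,
                t$total, x$config$lfdr_threshold,
                sum(t$disconnected)))
  }
  if (!is.null(x$group_contrast))
    cat("  differential edges:", x$group_contrast$tally$total, "\n")
  invisible(x)
}

#' Write / read a study report
#'
#' The report is serialized as a single JSON document under
#' \code{dir/report.json}, plus per-table TSV artifacts.
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if missing).
#' @return \code{read_study_report} returns the report as a plain list.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  for (nm in names(report$laterality))
    utils::write.table(report$laterality[[nm]],
                       file.path(dir, paste0("laterality_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "report.json"))
}

#' @rdname write_study_report
#' @export
read_study_report <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "report.json"), simplifyVector = TRUE)
}

# printed table cells: significant-edge counts by sign and gross topology,
# differential and asymmetry counts, and disconnected-node breakdowns
printed_tables <- function() {
  list(
    edges = list(
      controls = list(cells = c(LH_pos = 67, LH_neg = 7, RH_pos = 17,
                                RH_neg = 0, IH_pos = 10, IH_neg = 6),
                      total = 107, pct = 3.6,
                      disconnected = c(L = 6, R = 29), disc_total = 35),
      AD = list(cells = c(LH_pos = 26, LH_neg = 3, RH_pos = 9,
                          RH_neg = 0, IH_pos = 3, IH_neg = 1),
                total = 42, pct = 1.4,
                disconnected = c(L = 22, R = 32), disc_total = 54)),
    differences = list(
      "AD<Controls" = list(cells = c(LH = 12, RH = 1, IH = 7), total = 20),
      "AD>Controls" = list(cells = c(LH = 7, RH = 0, IH = 3), total = 10)),
    asymmetry = list(
      controls = list(cells = c("LH>RH" = 23, "LH<RH" = 3), total = 26),
      AD = list(cells = c("LH>RH" = 13, "LH<RH" = 3), total = 16)),
    n_pairs = 3003
  )
}

# build a synthetic edge_set with prescribed counts so the tally code
# paths are exercised end to end
mock_edge_set <- function(cells, atlas) {
  ec <- edge_classes(atlas)
  pick <- function(class, n) {
    rows <- ec[ec$class == class, , drop = FALSE][seq_len(n), ,
                                                  drop = FALSE]
    rows
  }
  mk <- function(class, n, sign) {
    if (n == 0)
      return(data.frame(i = integer(0), j = integer(0),
                        sign = character(0), class = character(0)))
    r <- pick(class, n)
    data.frame(i = r$i, j = r$j, sign = sign, class = class)
  }
  edges <- rbind(
    mk("intra-LH", cells["LH_pos"], "positive"),
    mk("intra-LH", cells["LH_neg"], "negative"),
    mk("intra-RH", cells["RH_pos"], "positive"),
    mk("intra-RH", cells["RH_neg"], "negative"),
    mk("interhemispheric", cells["IH_pos"], "positive"),
    mk("interhemispheric", cells["IH_neg"], "negative")
  )
  structure(list(edges = edges, threshold = 0.2, kind = "single-group",
                 n_nodes = atlas$n_nodes, disconnected = NULL),
            class = "edge_set")
}

#' Consistency check of the printed summary tables
#'
#' Recomputes every derivable total and percentage from the printed
#' per-cell counts of the edge, difference, and asymmetry tables --
#' running them through the same tally code used for real reports -- and
#' compares with the printed totals.
#'
#' @return data.frame of checks with columns \code{check},
#'   \code{computed}, \code{printed}, \code{ok}.
#' @examples
#' all(verify_paper_tallies()$ok)
#' @export
verify_paper_tallies <- function() {
  pt <- printed_tables()
  atlas <- default_atlas()
  checks <- list()
  add <- function(name, computed, printed)
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, computed = computed, printed = printed,
      ok = isTRUE(all.equal(computed, printed)))

  for (g in names(pt$edges)) {
    spec_g <- pt$edges[[g]]
    es <- mock_edge_set(spec_g$cells, atlas)
    tl <- edge_tally(es)
    add(paste0("edges_total_", g), tl$total, spec_g$total)
    add(paste0("edges_pct_", g),
        round(100 * tl$total / pt$n_pairs, 1), spec_g$pct)
    add(paste0("disconnected_total_", g),
        sum(spec_g$disconnected), spec_g$disc_total)
  }
  for (d in names(pt$differences)) {
    spec_d <- pt$differences[[d]]
    add(paste0("diff_total_", d), sum(spec_d$cells), spec_d$total)
  }
  add("diff_grand_total",
      sum(vapply(pt$differences, function(z) sum(z$cells), numeric(1))),
      20 + 10)
  for (g in names(pt$asymmetry)) {
    spec_a <- pt$asymmetry[[g]]
    add(paste0("asym_total_", g), sum(spec_a$cells), spec_a$total)
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
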