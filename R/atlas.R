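#' Brodmann-style ROI atlas for superficial white matter networks
#'
#' The analysis operates on 78 cortical regions: 39 Brodmann-style areas per
#' hemisphere, each assigned to one of five lobes (frontal, parietal,
#' paralimbic, temporal, occipital). Composite areas (1+2+3, 24+33, 29+30)
#' and the cuneus are atomic nodes. Left-hemisphere nodes come first,
#' followed by the right-hemisphere nodes in the same area order, so the
#' homotopic partner of node \code{i <= 39} is node \code{i + 39}.
#'
#' @return An object of class \code{swm_atlas}: a list with components
#'   \describe{
#'     \item{rois}{data.frame with columns \code{label}, \code{area},
#'       \code{hemisphere} ("L"/"R") and \code{lobe}.}
#'     \item{homotopic_pairs}{39 x 2 integer matrix of (left index,
#'       right index) pairs.}
#'     \item{n_nodes}{78.}
#'   }
#' @examples
#' atlas <- default_atlas()
#' atlas$n_nodes
#' table(atlas$rois$lobe) / 2
#' @export
default_atlas <- function() {
  areas <- c(
    # frontal (9)
    "4", "6", "8", "9", "10", "13", "44", "45", "46",
    # parietal (6)
    "1+2+3", "5", "7", "39", "40", "43",
    # paralimbic (14)
    "11", "23", "24+33", "25", "27", "28", "29+30", "31", "32", "34",
    "35", "36", "38", "47",
    # temporal (6)
    "20", "21", "22", "37", "41", "42",
    # occipital (4)
    "17", "18", "19", "Cuneus"
  )
  lobes <- rep(c("frontal", "parietal", "paralimbic", "temporal", "occipital"),
               times = c(9, 6, 14, 6, 4))
  rois <- data.frame(
    label = c(paste0("L_", areas), paste0("R_", areas)),
    area = rep(areas, 2),
    hemisphere = rep(c("L", "R"), each = 39L),
    lobe = rep(lobes, 2),
    stringsAsFactors = FALSE
  )
  atlas <- structure(
    list(
      rois = rois,
      homotopic_pairs = cbind(left = 1:39, right = 40:78),
      n_nodes = 78L
    ),
    class = "swm_atlas"
  )
  validate_atlas(atlas)
  atlas
}

#' Validate atlas invariants
#'
#' Checks the structural invariants of an atlas: 39 regions per hemisphere,
#' one lobe per region with the expected per-lobe counts, and a perfect
#' homotopic matching between hemispheres.
#'
#' @param atlas object to validate.
#' @return The atlas, invisibly; stops on violation.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "swm_atlas"))
  rois <- atlas$rois
  if (nrow(rois) != atlas$n_nodes)
    stop("atlas: roi table does not match n_nodes")
  hemi_counts <- table(rois$hemisphere)
  if (!identical(sort(names(hemi_counts)), c("L", "R")) ||
      any(hemi_counts != atlas$n_nodes / 2))
    stop("atlas: hemispheres are not balanced")
  expected <- c(frontal = 9L, parietal = 6L, paralimbic = 14L,
                temporal = 6L, occipital = 4L)
  for (h in c("L", "R")) {
    counts <- table(rois$lobe[rois$hemisphere == h])
    if (!all(names(expected) %in% names(counts)) ||
        any(counts[names(expected)] != expected))
      stop("atlas: lobe counts violated in hemisphere ", h)
  }
  hp <- atlas$homotopic_pairs
  if (nrow(hp) != atlas$n_nodes / 2)
    stop("atlas: homotopic pairing is not a perfect matching")
  if (any(rois$hemisphere[hp[, 1]] != "L") ||
      any(rois$hemisphere[hp[, 2]] != "R"))
    stop("atlas: homotopic pairs must map left onto right")
  if (any(rois$area[hp[, 1]] != rois$area[hp[, 2]]))
    stop("atlas: homotopic pairs must share the area label")
  if (anyDuplicated(hp[, 1]) || anyDuplicated(hp[, 2]))
    stop("atlas: homotopic pairing reuses a node")
  invisible(atlas)
}

#' @export
print.swm_atlas <- function(x, ...) {
  cat("ROI atlas:", x$n_nodes, "nodes (39 areas per hemisphere)\n")
  cat("Lobes (areas per hemisphere):\n")
  counts <- table(x$rois$lobe[x$rois$hemisphere == "L"])
  for (l in names(counts)) cat("  ", l, ": ", counts[[l]], "\n", sep = "")
  invisible(x)
}

#' Gross-topology class of an edge
#'
#' Classifies a node pair as left-intrahemispheric, right-intrahemispheric
#' or interhemispheric; this is the three-way split used when tallying
#' significant and differential edges.
#'
#' @param atlas an \code{swm_atlas}.
#' @param i,j distinct node indices in \code{1:atlas$n_nodes}. Vectorized.
#' @return character vector with values \code{"intra-LH"}, \code{"intra-RH"}
#'   or \code{"interhemispheric"}.
#' @examples
#' a <- default_atlas()
#' classify_edge(a, 1, 2)    # "intra-LH"
#' classify_edge(a, 1, 40)   # "interhemispheric"
#' @export
classify_edge <- function(atlas, i, j) {
  validate_atlas(atlas)
  if (length(i) != length(j)) stop("i and j must have the same length")
  bad <- !is.finite(i) | !is.finite(j) | i < 1 | j < 1 |
    i > atlas$n_nodes | j > atlas$n_nodes | i != round(i) | j != round(j)
  if (any(bad)) stop("invalid edge: node index out of range")
  if (any(i == j)) stop("invalid edge: self-edges are excluded")
  hi <- atlas$rois$hemisphere[i]
  hj <- atlas$rois$hemisphere[j]
  ifelse(hi != hj, "interhemispheric",
         ifelse(hi == "L", "intra-LH", "intra-RH"))
}

#' Enumerate all unordered node pairs with their edge class
#'
#' @param atlas an \code{swm_atlas}.
#' @return data.frame with columns \code{i}, \code{j} (i < j) and
#'   \code{class}; 3003 rows for the default atlas.
#' @export
edge_classes <- function(atlas) {
  k <- atlas$n_nodes
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             class = classify_edge(atlas, idx[, 1], idx[, 2]),
             stringsAsFactors = FALSE)
}

#' Write / read an atlas as JSON
#'
#' The serialized form stores one record per ROI (label, area, hemisphere,
#' lobe); the homotopic pairing is reconstructed from the shared area
#' labels and invariants are re-validated on read.
#'
#' @param atlas an \code{swm_atlas}.
#' @param path file path.
#' @return \code{read_atlas_json} returns the validated \code{swm_atlas}.
#' @export
write_atlas_json <- function(atlas, path) {
  validate_atlas(atlas)
  jsonlite::write_json(atlas$rois, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_atlas_json
#' @export
read_atlas_json <- function(path) {
  rois <- jsonlite::fromJSON(path)
  rois <- as.data.frame(rois, stringsAsFactors = FALSE)
  left <- which(rois$hemisphere == "L")
  right_all <- which(rois$hemisphere == "R")
  right <- right_all[match(rois$area[left], rois$area[right_all])]
  atlas <- structure(
    list(rois = rois,
         homotopic_pairs = cbind(left = left, right = right),
         n_nodes = nrow(rois)),
    class = "swm_atlas"
  )
  validate_atlas(atlas)
  atlas
}

#' Node sets of the ten lobe-hemisphere clusters
#'
#' @param atlas an \code{swm_atlas}.
#' @return named list of ten integer vectors (5 lobes x 2 hemispheres),
#'   e.g. \code{"frontal_L"}.
#' @export
lobe_clusters <- function(atlas) {
  validate_atlas(atlas)
  out <- list()
  for (l in c("frontal", "parietal", "paralimbic", "temporal", "occipital"))
    for (h in c("L", "R"))
      out[[paste(l, h, sep = "_")]] <-
        which(atlas$rois$lobe == l & atlas$rois$hemisphere == h)
  out
}
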