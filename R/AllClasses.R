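#' @import methods
NULL

#' Representational dissimilarity matrix
#'
#' An 8 x 8 (more generally n x n) symmetric dissimilarity matrix over
#' stimulus conditions with a zero diagonal.  Four kinds are used in the
#' pipeline: \code{"theoretical"} (binary between/within-category codes),
#' \code{"neural"} (1 - Pearson correlation between multivoxel patterns),
#' \code{"v1"} (1 - Pearson correlation between HMAX C1 feature vectors)
#' and \code{"behavioral"} (Euclidean distance between mean ratings).
#'
#' @slot values numeric matrix, symmetric with zero diagonal.
#' @slot kind character, one of \code{"theoretical"}, \code{"neural"},
#'   \code{"v1"}, \code{"behavioral"}.
#' @slot labels character vector of condition labels (row/column names).
#'
#' @seealso [theoreticalRDMs()], [neuralRDM()], [v1RDM()], [behavioralRDM()],
#'   [rdmVec()]
#' @export
setClass("RDM",
  representation(values = "matrix", kind = "character", labels = "character"),
  prototype(kind = "theoretical")
)

.rdm_kinds <- c("theoretical", "neural", "v1", "behavioral")

setValidity("RDM", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v) || nrow(v) != ncol(v)) {
    msgs <- c(msgs, "'values' must be a square numeric matrix")
  } else {
    if (any(!is.finite(v))) msgs <- c(msgs, "'values' must be finite")
    if (max(abs(v - t(v))) > 1e-8) msgs <- c(msgs, "'values' must be symmetric")
    if (max(abs(diag(v))) > 1e-8) msgs <- c(msgs, "diagonal must be zero")
    if (length(object@labels) != nrow(v)) {
      msgs <- c(msgs, "'labels' length must match matrix dimension")
    }
    if (identical(object@kind, "theoretical") &&
        !all(v %in% c(0, 1))) {
      msgs <- c(msgs, "theoretical RDMs must be binary (0/1)")
    }
  }
  if (!object@kind %in% .rdm_kinds) {
    msgs <- c(msgs, sprintf("'kind' must be one of: %s",
                            paste(.rdm_kinds, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an RDM object
#'
#' @param values square symmetric numeric matrix with zero diagonal.
#' @param kind RDM kind, see [RDM-class].
#' @param labels condition labels; defaults to the row names of
#'   \code{values}, or \code{s1..sn}.
#' @return An [RDM-class] object.
#' @export
RDM <- function(values, kind = "neural", labels = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("s", seq_len(nrow(values)))
  }
  dimnames(values) <- list(labels, labels)
  new("RDM", values = values, kind = kind, labels = labels)
}

#' Per-voxel statistic maps on a masked grid
#'
#' Container for one or more voxel-wise statistic images (searchlight RSA
#' coefficients, group t/p maps, classification accuracies, ...) defined on
#' the in-mask voxels of a 3D grid.  Values are stored as a voxels x
#' statistics matrix; \code{maskIdx} gives the linear grid index of each row.
#'
#' @slot dim integer(3), grid dimensions.
#' @slot maskIdx integer vector of in-mask linear voxel indices.
#' @slot values numeric matrix, \code{length(maskIdx)} rows.
#' @slot statNames character, column names of \code{values}.
#' @export
setClass("VoxelMap",
  representation(dim = "integer", maskIdx = "integer",
                 values = "matrix", statNames = "character")
)

setValidity("VoxelMap", function(object) {
  msgs <- character()
  if (length(object@dim) != 3L) msgs <- c(msgs, "'dim' must have length 3")
  if (nrow(object@values) != length(object@maskIdx)) {
    msgs <- c(msgs, "'values' must have one row per mask voxel")
  }
  if (ncol(object@values) != length(object@statNames)) {
    msgs <- c(msgs, "'statNames' must name the value columns")
  }
  if (length(object@maskIdx) &&
      (min(object@maskIdx) < 1L || max(object@maskIdx) > prod(object@dim))) {
    msgs <- c(msgs, "'maskIdx' out of grid range")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a VoxelMap
#'
#' @param values numeric vector or voxels x statistics matrix.
#' @param mask logical 3D array, or an integer vector of linear indices in
#'   which case \code{dim} must be given.
#' @param statNames column names; defaults to existing column names or
#'   \code{stat1..statm}.
#' @param dim grid dimensions when \code{mask} is an index vector.
#' @return A [VoxelMap-class].
#' @export
VoxelMap <- function(values, mask, statNames = NULL, dim = NULL) {
  if (is.array(mask) && is.logical(mask)) {
    dim <- dim(mask)
    maskIdx <- which(mask)
  } else {
    if (is.null(dim)) stop("'dim' required when mask is an index vector")
    maskIdx <- as.integer(mask)
  }
  values <- as.matrix(values)
  if (is.null(statNames)) {
    statNames <- colnames(values)
    if (is.null(statNames)) statNames <- paste0("stat", seq_len(ncol(values)))
  }
  colnames(values) <- statNames
  new("VoxelMap", dim = as.integer(dim), maskIdx = as.integer(maskIdx),
      values = values, statNames = statNames)
}

#' Searchlight neighborhood definition
#'
#' For every in-mask voxel, the indices (into the mask-voxel ordering) of
#' its k nearest in-mask voxels by Euclidean grid distance, ties broken by
#' ascending linear voxel index.  Each neighborhood contains its own center.
#'
#' @slot dim integer(3) grid dimensions.
#' @slot maskIdx integer linear indices of mask voxels (centers).
#' @slot neighbors integer matrix, k x n_voxels; column v lists the
#'   mask-voxel indices in the searchlight centered on voxel v.
#' @slot k integer, voxels per searchlight.
#' @seealso [defineSearchlights()]
#' @export
setClass("Searchlights",
  representation(dim = "integer", maskIdx = "integer",
                 neighbors = "matrix", k = "integer")
)

setValidity("Searchlights", function(object) {
  msgs <- character()
  if (nrow(object@neighbors) != object@k) {
    msgs <- c(msgs, "'neighbors' must have k rows")
  }
  if (ncol(object@neighbors) != length(object@maskIdx)) {
    msgs <- c(msgs, "'neighbors' must have one column per mask voxel")
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulated single-subject block-design acquisition
#'
#' Holds everything the analysis stages need for one synthetic participant:
#' per-run BOLD series, per-run event timelines and nuisance regressors, the
#' gray-matter analog mask, and the planted ground truth.
#'
#' @slot runs list of volumes x voxels numeric matrices (in-mask voxels).
#' @slot timelines list of per-run event data frames (onset, duration,
#'   trial_type).
#' @slot nuisance list of volumes x 6 synthetic motion-regressor matrices.
#' @slot mask logical 3D array (tissue probability > threshold).
#' @slot tissueProb numeric 3D array in [0, 1].
#' @slot truth numeric voxels x 8 matrix of planted per-stimulus amplitudes.
#' @slot effects list, the effect specification used.
#' @slot design list, the design specification used.
#' @slot labels data frame of the 8 stimulus labels.
#' @slot seed integer seed this subject was generated from.
#' @export
setClass("SubjectData",
  representation(runs = "list", timelines = "list", nuisance = "list",
                 mask = "array", tissueProb = "array", truth = "matrix",
                 effects = "list", design = "list", labels = "data.frame",
                 seed = "integer")
)

setValidity("SubjectData", function(object) {
  msgs <- character()
  if (!length(object@runs)) msgs <- c(msgs, "no runs")
  nv <- vapply(object@runs, nrow, 0L)
  if (length(unique(nv)) > 1) msgs <- c(msgs, "runs differ in volume count")
  if (!any(object@mask)) msgs <- c(msgs, "mask is empty")
  if (length(msgs)) msgs else TRUE
})

#' Labeled supra-threshold clusters
#'
#' Connected components of a thresholded statistic map, with sizes, peak
#' statistics and (optionally) Monte Carlo corrected cluster-level p-values.
#'
#' @slot dim integer(3) grid dimensions.
#' @slot labels integer vector over mask voxels; 0 = sub-threshold.
#' @slot maskIdx integer linear indices of mask voxels.
#' @slot table data frame with one row per cluster: \code{cluster},
#'   \code{size}, \code{peak}, \code{peak_voxel} and, after correction,
#'   \code{p} and \code{significant}.
#' @slot connectivity integer; 6, 18 or 26.
#' @export
setClass("ClusterSet",
  representation(dim = "integer", labels = "integer", maskIdx = "integer",
                 table = "data.frame", connectivity = "integer")
)

setValidity("ClusterSet", function(object) {
  msgs <- character()
  if (length(object@labels) != length(object@maskIdx)) {
    msgs <- c(msgs, "'labels' must match 'maskIdx' length")
  }
  if (!object@connectivity %in% c(6L, 18L, 26L)) {
    msgs <- c(msgs, "'connectivity' must be 6, 18 or 26")
  }
  if (nrow(object@table) && any(object@table$size < 1)) {
    msgs <- c(msgs, "cluster sizes must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})
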