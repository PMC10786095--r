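# Accessor generics and show methods for the package's S4 containers.

#' @describeIn RDM-class dissimilarity matrix values
#' @param object,x an object of the documented class
#' @export
setGeneric("rdmValues", function(object) standardGeneric("rdmValues"))
#' @export
setMethod("rdmValues", "RDM", function(object) object@values)

#' @describeIn RDM-class RDM kind
#' @export
setGeneric("rdmKind", function(object) standardGeneric("rdmKind"))
#' @export
setMethod("rdmKind", "RDM", function(object) object@kind)

#' @describeIn RDM-class condition labels
#' @export
setGeneric("rdmLabels", function(object) standardGeneric("rdmLabels"))
#' @export
setMethod("rdmLabels", "RDM", function(object) object@labels)

setMethod("show", "RDM", function(object) {
  cat(sprintf("RDM (%s) over %d conditions\n", object@kind,
              nrow(object@values)))
  print(round(object@values, 3))
})

#' @describeIn VoxelMap-class voxels x statistics value matrix
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @export
setMethod("mapValues", "VoxelMap", function(object) object@values)

#' @describeIn VoxelMap-class linear grid indices of mask voxels
#' @export
setGeneric("maskIndices", function(object) standardGeneric("maskIndices"))
#' @export
setMethod("maskIndices", "VoxelMap", function(object) object@maskIdx)
#' @export
setMethod("maskIndices", "Searchlights", function(object) object@maskIdx)
#' @export
setMethod("maskIndices", "ClusterSet", function(object) object@maskIdx)

#' @describeIn VoxelMap-class grid dimensions
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))
#' @export
setMethod("gridDim", "VoxelMap", function(object) object@dim)
#' @export
setMethod("gridDim", "Searchlights", function(object) object@dim)
#' @export
setMethod("gridDim", "ClusterSet", function(object) object@dim)

setMethod("show", "VoxelMap", function(object) {
  cat(sprintf("VoxelMap: %d voxels on a %s grid; statistics: %s\n",
              length(object@maskIdx), paste(object@dim, collapse = "x"),
              paste(object@statNames, collapse = ", ")))
})

setMethod("show", "Searchlights", function(object) {
  cat(sprintf("Searchlights: %d centers, k = %d, grid %s\n",
              length(object@maskIdx), object@k,
              paste(object@dim, collapse = "x")))
})

#' @describeIn ClusterSet-class cluster summary table
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))
#' @export
setMethod("clusterTable", "ClusterSet", function(object) object@table)

#' @describeIn ClusterSet-class per-mask-voxel integer cluster labels
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @export
setMethod("clusterLabels", "ClusterSet", function(object) object@labels)

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters (connectivity %d)\n",
              nrow(object@table), object@connectivity))
  if (nrow(object@table)) print(utils::head(object@table, 10))
})

setMethod("show", "SubjectData", function(object) {
  cat(sprintf(
    "SubjectData: %d runs x %d volumes, %d mask voxels (grid %s), seed %d\n",
    length(object@runs), nrow(object@runs[[1]]), sum(object@mask),
    paste(dim(object@mask), collapse = "x"), object@seed))
})

#' @describeIn SubjectData-class per-run BOLD series (volumes x voxels)
#' @export
setGeneric("subjectRuns", function(object) standardGeneric("subjectRuns"))
#' @export
setMethod("subjectRuns", "SubjectData", function(object) object@runs)

#' @describeIn SubjectData-class planted per-stimulus amplitude truth
#' @export
setGeneric("subjectTruth", function(object) standardGeneric("subjectTruth"))
#' @export
setMethod("subjectTruth", "SubjectData", function(object) object@truth)

#' @describeIn SubjectData-class gray-matter analog mask
#' @export
setGeneric("subjectMask", function(object) standardGeneric("subjectMask"))
#' @export
setMethod("subjectMask", "SubjectData", function(object) object@mask)
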