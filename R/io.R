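# File-format interfaces: NIfTI volumes, labeled RDM CSVs, TSV tables.

#' Expand a VoxelMap statistic to a full 3D array
#'
#' @param map a [VoxelMap-class].
#' @param stat statistic name or column index (default 1).
#' @param fill value outside the mask (default NA).
#' @return 3D numeric array.
#' @export
mapToArray <- function(map, stat = 1, fill = NA_real_) {
  arr <- array(fill, map@dim)
  arr[map@maskIdx] <- map@values[, stat]
  arr
}

#' Write a VoxelMap statistic as NIfTI-1
#'
#' @param map a [VoxelMap-class].
#' @param path output path (.nii or .nii.gz).
#' @param stat statistic name or index.
#' @return The path, invisibly.
#' @export
writeMapNifti <- function(map, path, stat = 1) {
  RNifti::writeNifti(mapToArray(map, stat, fill = 0), path)
  invisible(path)
}

#' Write a binary mask as NIfTI-1
#'
#' @param mask logical 3D array.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMaskNifti <- function(mask, path) {
  RNifti::writeNifti(array(as.numeric(mask), dim(mask)), path)
  invisible(path)
}

#' Read a NIfTI volume as an array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
readVolumeNifti <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Write an RDM as a labeled CSV
#'
#' @param rdm an [RDM-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeRDMcsv <- function(rdm, path) {
  m <- rdm@values
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a labeled RDM CSV
#'
#' @param path CSV path written by [writeRDMcsv()].
#' @param kind RDM kind.
#' @return An [RDM-class].
#' @export
readRDMcsv <- function(path, kind = "neural") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  RDM(as.matrix(df), kind = kind, labels = rownames(df))
}

#' Write a ratings table as TSV
#'
#' @param ratings a \code{RatingTable}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeRatingsTSV <- function(ratings, path) {
  utils::write.table(as.data.frame(ratings), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster table as TSV
#'
#' @param cs a [ClusterSet-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeClusterTSV <- function(cs, path) {
  utils::write.table(cs@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
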