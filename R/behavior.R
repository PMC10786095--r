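# Linking behavioral rating RDMs to cluster-restricted neural RDMs.

#' Neural RDM of one cluster
#'
#' The 1 - Pearson pattern dissimilarity computed over the cluster's
#' voxels only.
#'
#' @param tmaps condition t-maps ([VoxelMap-class] or voxels x 8 matrix).
#' @param voxels integer indices (into the mask-voxel ordering) of the
#'   cluster's voxels; at least 2.
#' @return An [RDM-class] of kind \code{"neural"}.
#' @export
clusterNeuralRDM <- function(tmaps, voxels) {
  tm <- if (is(tmaps, "VoxelMap")) tmaps@values else as.matrix(tmaps)
  if (length(voxels) < 2) stop("cluster must contain at least 2 voxels")
  neuralRDM(tm[voxels, , drop = FALSE])
}

#' Correlate behavioral and neural RDMs across subjects
#'
#' Per subject and cluster, the correlation between the vectorized
#' behavioral RDM and the cluster's neural RDM; the correlations are
#' Fisher-transformed and entered into a one-sample t-test against zero,
#' with BH-FDR correction across clusters.  Subjects whose behavioral RDM
#' has zero variance (all ratings equal) are excluded with a warning.
#'
#' @param neural list (subjects) of lists (clusters) of neural
#'   [RDM-class]s.
#' @param behavioral list (subjects) of behavioral [RDM-class]s for one
#'   attribute.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param q FDR level.
#' @return Data frame: one row per cluster with \code{mean_z}, \code{t},
#'   \code{p}, \code{fdr_significant}, \code{n_subjects}; attribute
#'   \code{correlations} (subjects x clusters).
#' @export
behaviorNeuralLink <- function(neural, behavioral, method = "pearson",
                               q = 0.05) {
  nS <- length(neural)
  stopifnot(nS == length(behavioral), nS >= 2)
  behVec <- lapply(behavioral, rdmVec)
  usable <- vapply(behVec, function(v) stats::sd(v) > 0, NA)
  if (!all(usable)) {
    warning(sprintf("%d subject(s) excluded: zero-variance behavioral RDM",
                    sum(!usable)))
  }
  clusters <- names(neural[[1]])
  if (is.null(clusters)) clusters <- paste0("cluster", seq_along(neural[[1]]))
  cors <- matrix(NA_real_, nS, length(clusters),
                 dimnames = list(NULL, clusters))
  for (s in which(usable)) {
    for (ci in seq_along(clusters)) {
      cors[s, ci] <- stats::cor(behVec[[s]], rdmVec(neural[[s]][[ci]]),
                                method = method)
    }
  }
  rows <- NULL
  for (ci in seq_along(clusters)) {
    z <- fisherZ(cors[usable, ci])
    if (stats::sd(z) == 0) {      # identical correlations across subjects
      tval <- if (mean(z) == 0) 0 else sign(mean(z)) * 100
      pval <- if (mean(z) > 0) 0 else 1
    } else {
      tt <- stats::t.test(z, mu = 0, alternative = "greater")
      tval <- unname(tt$statistic)
      pval <- tt$p.value
    }
    rows <- rbind(rows, data.frame(cluster = clusters[ci],
                                   mean_z = mean(z),
                                   t = tval,
                                   p = pval,
                                   n_subjects = sum(usable)))
  }
  rows$fdr_significant <- fdrBH(rows$p, q)
  attr(rows, "correlations") <- cors
  rows
}
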