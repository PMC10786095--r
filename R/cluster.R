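# Voxel-wise thresholding, 3D connected components, sign-flip Monte Carlo
# cluster correction, and BH-FDR utilities.

#' Threshold specification for cluster inference
#'
#' @param voxel_p initial voxel-wise p threshold (default 0.001).
#' @param n_iter Monte Carlo iterations (default 5000; the test profile
#'   uses 500).
#' @param alpha cluster-level significance level.
#' @param connectivity 6, 18 or 26 neighborhood.
#' @param seed integer seed for the sign flips.
#' @param tail \code{"pos"} (one-sided, positive direction of interest) or
#'   \code{"two"}.
#' @return A \code{ThresholdSpec} list.
#' @export
thresholdSpec <- function(voxel_p = 0.001, n_iter = 5000, alpha = 0.05,
                          connectivity = 26, seed = 1, tail = c("pos", "two")) {
  tail <- match.arg(tail)
  if (voxel_p <= 0 || voxel_p >= 1) stop("'voxel_p' must be in (0, 1)")
  if (n_iter < 100) stop("'n_iter' must be >= 100")
  structure(list(voxel_p = voxel_p, n_iter = as.integer(n_iter),
                 alpha = alpha, connectivity = as.integer(connectivity),
                 seed = as.integer(seed), tail = tail),
            class = "ThresholdSpec")
}

#' Voxel-wise threshold of a t map
#'
#' Keeps a voxel iff its p-value beats \code{voxel_p}; one-sided positive
#' by default.  NA t values are dropped; +Inf-like capped values are kept.
#'
#' @param t numeric vector of t statistics (mask voxels).
#' @param dof degrees of freedom (>= 1).
#' @param voxel_p threshold p.
#' @param tail \code{"pos"} or \code{"two"}.
#' @return Logical vector.
#' @export
voxelThreshold <- function(t, dof, voxel_p = 0.001, tail = c("pos", "two")) {
  tail <- match.arg(tail)
  if (dof < 1) stop("'dof' must be >= 1")
  crit <- if (tail == "pos") {
    stats::qt(1 - voxel_p, df = dof)
  } else {
    stats::qt(1 - voxel_p / 2, df = dof)
  }
  keep <- if (tail == "pos") t > crit else abs(t) > crit
  keep & !is.na(t)
}

# Neighbor offsets for the chosen connectivity.
.connOffsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[ord == 1, , drop = FALSE],
         "18" = off[ord <= 2, , drop = FALSE],
         "26" = off,
         stop("connectivity must be 6, 18 or 26"))
}

#' Label supra-threshold clusters
#'
#' Connected components of a binary map over mask voxels under the chosen
#' 3D connectivity; components are labeled in order of their minimum linear
#' voxel index.
#'
#' @param binary logical vector over mask voxels.
#' @param maskIdx linear grid indices of the mask voxels.
#' @param dim integer(3) grid dimensions.
#' @param connectivity 6, 18 or 26.
#' @param stat optional statistic vector for peak values.
#' @return A [ClusterSet-class].
#' @export
labelClusters <- function(binary, maskIdx, dim, connectivity = 26,
                          stat = NULL) {
  V <- length(maskIdx)
  stopifnot(length(binary) == V)
  labels <- integer(V)
  supra <- which(binary)
  tab <- data.frame(cluster = integer(0), size = integer(0),
                    peak = numeric(0), peak_voxel = integer(0))
  if (length(supra)) {
    off <- .connOffsets(connectivity)
    lut <- integer(prod(dim))
    lut[maskIdx[supra]] <- supra
    co <- gridCoords(maskIdx, dim)
    nextLab <- 0L
    for (s in supra) {       # ascending order => labels by min voxel index
      if (labels[s] != 0L) next
      nextLab <- nextLab + 1L
      queue <- s
      labels[s] <- nextLab
      head <- 1L
      while (head <= length(queue)) {
        v <- queue[head]; head <- head + 1L
        nb <- sweep(off, 2, co[v, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dim[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dim[1] +
          (nb[ok, 3] - 1L) * dim[1] * dim[2]
        cand <- lut[lin]
        cand <- cand[cand != 0L]
        cand <- cand[labels[cand] == 0L]
        if (length(cand)) {
          labels[cand] <- nextLab
          queue <- c(queue, cand)
        }
      }
    }
    sizes <- tabulate(labels, nextLab)
    peak <- rep(NA_real_, nextLab)
    peakVox <- rep(NA_integer_, nextLab)
    if (!is.null(stat)) {
      for (cl in seq_len(nextLab)) {
        vx <- which(labels == cl)
        peak[cl] <- max(stat[vx])
        peakVox[cl] <- maskIdx[vx[which.max(stat[vx])]]
      }
    }
    tab <- data.frame(cluster = seq_len(nextLab), size = sizes,
                      peak = peak, peak_voxel = peakVox)
  }
  new("ClusterSet", dim = as.integer(dim), labels = labels,
      maskIdx = as.integer(maskIdx), table = tab,
      connectivity = as.integer(connectivity))
}

# Max cluster size of a binary map: cheap path for the Monte Carlo loop.
.maxClusterSize <- function(binary, maskIdx, dim, off, co, lutTemplate) {
  supra <- which(binary)
  if (!length(supra)) return(0L)
  lut <- lutTemplate
  lut[maskIdx[supra]] <- supra
  labels <- integer(length(binary))
  best <- 0L
  lab <- 0L
  for (s in supra) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    head <- 1L
    size <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      nb <- sweep(off, 2, co[v, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim[1] &
        nb[, 2] >= 1 & nb[, 2] <= dim[2] &
        nb[, 3] >= 1 & nb[, 3] <= dim[3]
      if (!any(ok)) next
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dim[1] +
        (nb[ok, 3] - 1L) * dim[1] * dim[2]
      cand <- lut[lin]
      cand <- cand[cand != 0L]
      cand <- cand[labels[cand] == 0L]
      if (length(cand)) {
        labels[cand] <- lab
        queue <- c(queue, cand)
        size <- size + length(cand)
      }
    }
    if (size > best) best <- size
  }
  best
}

#' Sign-flip Monte Carlo cluster-level correction
#'
#' Builds the null distribution of the maximum supra-threshold cluster
#' size by randomly flipping the sign of each subject's map (valid under a
#' symmetric null), recomputing the group t map, thresholding at
#' \code{voxel_p} and recording the largest cluster.  The observed
#' clusters' corrected p is \code{(1 + #(null max >= size)) / (1 + n_iter)}.
#'
#' @param subjectMaps list of subject [VoxelMap-class]s (single statistic)
#'   or an subjects x voxels matrix.
#' @param spec a [thresholdSpec()].
#' @param maskIdx,dim grid geometry (taken from the maps when omitted).
#' @param fisher Fisher-transform subject values before testing.
#' @return A [ClusterSet-class] whose table gains \code{p} and
#'   \code{significant}; attributes \code{nullMax} (the null sizes) and
#'   \code{tmap}.
#' @export
monteCarloCluster <- function(subjectMaps, spec = thresholdSpec(),
                              maskIdx = NULL, dim = NULL, fisher = FALSE) {
  if (is.list(subjectMaps)) {
    if (is.null(maskIdx)) maskIdx <- subjectMaps[[1]]@maskIdx
    if (is.null(dim)) dim <- subjectMaps[[1]]@dim
    M <- t(vapply(subjectMaps, function(m) m@values[, 1],
                  numeric(length(maskIdx))))
  } else {
    M <- subjectMaps
    if (is.null(maskIdx) || is.null(dim)) {
      stop("'maskIdx' and 'dim' are required for matrix input")
    }
  }
  if (nrow(M) < 2) stop("need at least 2 subjects")
  if (fisher) M <- fisherZ(M)
  ok <- colSums(is.na(M)) == 0
  M[, !ok] <- 0                      # skipped voxels cannot enter clusters
  n <- nrow(M)
  df <- n - 1L
  ssq <- colSums(M^2)
  tOf <- function(m) {
    sd2 <- pmax(ssq - n * m^2, 0) / df
    tt <- m / sqrt(sd2 / n)
    tt[sd2 == 0] <- sign(m[sd2 == 0]) * 100
    tt
  }
  tobs <- tOf(colMeans(M))
  tobs[!ok] <- NA
  keep <- voxelThreshold(tobs, df, spec$voxel_p, spec$tail)
  cs <- labelClusters(keep, maskIdx, dim, spec$connectivity, stat = tobs)
  off <- .connOffsets(spec$connectivity)
  co <- gridCoords(maskIdx, dim)
  lutTemplate <- integer(prod(dim))
  set.seed(spec$seed)
  nullMax <- integer(spec$n_iter)
  for (it in seq_len(spec$n_iter)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    tt <- tOf(colMeans(M * s))
    kp <- voxelThreshold(tt, df, spec$voxel_p, spec$tail)
    nullMax[it] <- .maxClusterSize(kp, maskIdx, dim, off, co, lutTemplate)
  }
  tab <- cs@table
  if (nrow(tab)) {
    tab$p <- vapply(tab$size, function(sz) {
      (1 + sum(nullMax >= sz)) / (1 + spec$n_iter)
    }, 0)
    tab$significant <- tab$p < spec$alpha
  } else {
    tab$p <- numeric(0)
    tab$significant <- logical(0)
  }
  out <- new("ClusterSet", dim = cs@dim, labels = cs@labels,
             maskIdx = cs@maskIdx, table = tab,
             connectivity = cs@connectivity)
  attr(out, "nullMax") <- nullMax
  attr(out, "tmap") <- tobs
  out
}

#' Significant-voxel binary map of a corrected ClusterSet
#'
#' @param cs a [ClusterSet-class] with corrected p-values.
#' @return Logical vector over mask voxels (TRUE inside significant
#'   clusters).
#' @export
significantVoxels <- function(cs) {
  tab <- cs@table
  sig <- tab$cluster[tab$significant]
  cs@labels %in% sig
}

#' Benjamini-Hochberg FDR rejections
#'
#' Step-up procedure at level q.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level.
#' @return Logical rejection flags (empty input gives empty output).
#' @export
fdrBH <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Dice overlap of two binary maps
#'
#' dc = 2 N_C / (N_1 + N_2); 1 indicates complete congruence, 0 none.
#' Defined as 0 (flagged) when both maps are empty.
#'
#' @param mask1,mask2 logical vectors/arrays on the same grid.
#' @return A \code{DiceResult} list: \code{n1}, \code{n2}, \code{n_common},
#'   \code{dc}, \code{both_empty}.
#' @export
dice <- function(mask1, mask2) {
  if (length(mask1) != length(mask2)) stop("maps are on different grids")
  n1 <- sum(mask1)
  n2 <- sum(mask2)
  nc <- sum(mask1 & mask2)
  bothEmpty <- (n1 + n2) == 0
  dc <- if (bothEmpty) 0 else 2 * nc / (n1 + n2)
  structure(list(n1 = n1, n2 = n2, n_common = nc, dc = dc,
                 both_empty = bothEmpty), class = "DiceResult")
}
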