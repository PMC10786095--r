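# Searchlight decoding of the attribute dichotomies with leave-one-run-out
# cross-validation and cluster-level accuracy statistics.

#' Demean a multivoxel pattern
#'
#' Subtracts each pattern's mean over (searchlight) voxels, removing
#' amplitude differences between conditions; patterns are rows.
#'
#' @param x samples x voxels matrix (or a single pattern vector).
#' @return Same shape, each pattern with zero mean over voxels.
#' @export
demeanPattern <- function(x) {
  if (is.null(dim(x))) return(x - mean(x))
  x - rowMeans(x)
}

#' Searchlight linear SVM decoding with leave-one-run-out folds
#'
#' For every searchlight (optionally a subset of centers), the 48 per-run
#' condition beta patterns are demeaned across searchlight voxels, split
#' into the attribute's two classes (4 stimuli each), and classified with
#' a linear support vector machine trained on 5 runs and tested on the
#' held-out run; the mean test accuracy over the 6 folds is assigned to
#' the center voxel.
#'
#' @param betas voxels x (8 * n_runs) per-run condition beta matrix
#'   ([runBetas()] output).
#' @param condition,run length-48 labels of the beta columns.
#' @param labels stimulus label data frame.
#' @param attribute dichotomy to decode (facing, gender or emotion).
#' @param sl a [Searchlights-class].
#' @param centers optional integer subset of mask-voxel indices at which
#'   to compute the map (default all).
#' @param cost linear SVM cost parameter (default 1).
#' @param demean demean each pattern across searchlight voxels (default
#'   TRUE).
#' @return A [VoxelMap-class] of cross-validated accuracies (NA at
#'   non-computed centers).
#' @export
searchlightClassify <- function(betas, condition, run, labels, attribute,
                                sl, centers = NULL, cost = 1, demean = TRUE) {
  V <- ncol(sl@neighbors)
  if (is.null(centers)) centers <- seq_len(V)
  cls <- attributeSigns(labels)[match(condition, labels$id), attribute]
  y <- factor(cls, levels = c(-1, 1))
  runs <- sort(unique(run))
  acc <- rep(NA_real_, V)
  degenerate <- 0L
  for (v in centers) {
    P <- t(betas[sl@neighbors[, v], , drop = FALSE])   # samples x voxels
    if (demean) P <- demeanPattern(P)
    foldAcc <- numeric(length(runs))
    for (fi in seq_along(runs)) {
      test <- run == runs[fi]
      Xtr <- P[!test, , drop = FALSE]
      if (max(apply(Xtr, 2, function(cc) diff(range(cc)))) == 0) {
        foldAcc[fi] <- 0.5
        degenerate <- degenerate + 1L
        next
      }
      fit <- e1071::svm(Xtr, y[!test], kernel = "linear", cost = cost,
                        scale = FALSE)
      pred <- stats::predict(fit, P[test, , drop = FALSE])
      foldAcc[fi] <- mean(pred == y[test])
    }
    acc[v] <- mean(foldAcc)
  }
  if (degenerate > 0) {
    warning(sprintf("%d degenerate training folds scored at chance",
                    degenerate))
  }
  VoxelMap(acc, sl@maskIdx, statNames = paste0("accuracy_", attribute),
           dim = sl@dim)
}

#' Mean classification accuracy per cluster
#'
#' @param map an accuracy [VoxelMap-class].
#' @param clusters a [ClusterSet-class] on the same grid.
#' @param which cluster ids (default: significant clusters, or all when no
#'   correction was run).
#' @return Named numeric vector of per-cluster mean accuracies.
#' @export
clusterAccuracy <- function(map, clusters, which = NULL) {
  if (!identical(map@dim, clusters@dim)) stop("grids differ")
  tab <- clusters@table
  if (is.null(which)) {
    which <- if ("significant" %in% names(tab)) {
      tab$cluster[tab$significant]
    } else {
      tab$cluster
    }
  }
  out <- vapply(which, function(cl) {
    vx <- which(clusters@labels == cl)
    if (!length(vx)) stop(sprintf("cluster %d is empty", cl))
    vals <- map@values[vx, 1]
    if (all(is.na(vals))) stop(sprintf("cluster %d has no computed accuracies", cl))
    mean(vals, na.rm = TRUE)
  }, 0)
  stats::setNames(out, paste0("cluster", which))
}

#' Cluster-level accuracy statistics and display levels
#'
#' For every cluster of an attribute's RSA network: a one-sample t-test of
#' its own-attribute accuracies against chance (0.5), paired t-tests of
#' the own attribute against each of the other two, BH-FDR correction per
#' attribute network, and the three display levels: (1) above chance,
#' (2) additionally higher than one other attribute, (3) higher than both.
#'
#' @param accuracies data frame with columns \code{subject}, \code{cluster},
#'   \code{attribute} (the decoded dichotomy) and \code{accuracy}.
#' @param network named character: the attribute whose RSA identified each
#'   cluster (names = cluster ids).
#' @param q FDR level.
#' @return Data frame: one row per cluster with mean accuracies, test
#'   statistics, FDR flags and \code{level} (0--3).
#' @export
accuracyTests <- function(accuracies, network, q = 0.05) {
  # one-sided one-sample t robust to zero-variance inputs (constant
  # accuracies give t = 0, p = 1 rather than an error)
  safeT <- function(x, mu = 0) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      d <- mean(x) - mu
      t <- if (d == 0) 0 else sign(d) * 100
      return(list(t = t, p = if (d > 0) 0 else 1))
    }
    tt <- stats::t.test(x, mu = mu, alternative = "greater")
    list(t = unname(tt$statistic), p = tt$p.value)
  }
  clusters <- names(network)
  allAttrs <- unique(accuracies$attribute)
  rows <- NULL
  for (cl in clusters) {
    own <- network[[cl]]
    sub <- accuracies[accuracies$cluster == cl, , drop = FALSE]
    wide <- stats::reshape(sub, idvar = "subject", timevar = "attribute",
                           direction = "wide")
    ownAcc <- wide[[paste0("accuracy.", own)]]
    tChance <- safeT(ownAcc, 0.5)
    prow <- data.frame(cluster = cl, network = own,
                       mean_acc = mean(ownAcc),
                       t_chance = tChance$t,
                       p_chance = tChance$p)
    # canonical column set across networks; the own attribute's own
    # comparison columns stay NA
    for (a in allAttrs) {
      if (a == own) {
        prow[[paste0("t_vs_", a)]] <- NA_real_
        prow[[paste0("p_vs_", a)]] <- NA_real_
      } else {
        tt <- safeT(ownAcc - wide[[paste0("accuracy.", a)]], 0)
        prow[[paste0("t_vs_", a)]] <- tt$t
        prow[[paste0("p_vs_", a)]] <- tt$p
      }
    }
    rows <- rbind(rows, prow)
  }
  # FDR within each attribute network across all its clusters and tests
  pcols <- grep("^p_", names(rows), value = TRUE)
  for (a in unique(rows$network)) {
    ix <- which(rows$network == a)
    pv <- unlist(rows[ix, pcols])
    ok <- !is.na(pv)
    flags <- rep(NA, length(pv))
    flags[ok] <- fdrBH(pv[ok], q)
    flags <- matrix(flags, nrow = length(ix))
    colnames(flags) <- sub("^p_", "sig_", pcols)
    for (cn in colnames(flags)) rows[ix, cn] <- flags[, cn]
  }
  sigOther <- rowSums(as.matrix(rows[, grep("^sig_vs_", names(rows)),
                                     drop = FALSE]), na.rm = TRUE)
  rows$level <- ifelse(!rows$sig_chance, 0L,
                       ifelse(sigOther >= 2, 3L,
                              ifelse(sigOther == 1, 2L, 1L)))
  rownames(rows) <- NULL
  rows
}
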