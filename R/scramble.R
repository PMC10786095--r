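# Hierarchy analysis: RSA with the two non-target theoretical RDMs
# scrambled, permutation-averaged z maps, and Dice overlap with the
# standard multiple-regression RSA maps.

#' Scrambling plan for one target attribute
#'
#' @param target attribute whose theoretical RDM stays intact
#'   (facing, gender or emotion).
#' @param n_perm number of scrambles (default 1000; the test profile uses
#'   100).
#' @param seed integer seed for the label permutations.
#' @param granularity \code{"labels"} (joint row/column permutation of
#'   condition labels, the default) or \code{"entries"} (shuffle the 28
#'   lower-triangle entries; sensitivity variant).
#' @param zscore \code{"fisher"} (atanh of the coefficient map, matching
#'   the main RSA; default) or \code{"spatial"} (z-score the map across
#'   voxels per permutation).
#' @return A \code{ScramblePlan} list.
#' @export
scramblePlan <- function(target = c("facing", "gender", "emotion"),
                         n_perm = 1000, seed = 1,
                         granularity = c("labels", "entries"),
                         zscore = c("fisher", "spatial")) {
  target <- match.arg(target)
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  structure(list(target = target, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 granularity = match.arg(granularity),
                 zscore = match.arg(zscore)),
            class = "ScramblePlan")
}

#' Scrambled-RDM searchlight RSA for one subject
#'
#' For each of \code{n_perm} seeded draws, the two non-target theoretical
#' RDMs are independently scrambled, the 4-predictor searchlight regression
#' is re-fit, and the target attribute's coefficient map is transformed to
#' a z map; the permutation-mean z map is returned.
#'
#' @param tmaps subject condition t-maps (or NULL when \code{Y} is given).
#' @param theoretical named list of three theoretical RDMs.
#' @param v1 the V1 predictor RDM.
#' @param sl a [Searchlights-class].
#' @param plan a [scramblePlan()].
#' @param Y optional precomputed [neuralRDMVectors()] matrix (strongly
#'   recommended when calling repeatedly: the neural RDMs do not depend on
#'   the scrambles).
#' @return A [VoxelMap-class] with the averaged z statistic for the target
#'   attribute.
#' @export
scrambledRSA <- function(tmaps, theoretical, v1, sl, plan, Y = NULL) {
  stopifnot(inherits(plan, "ScramblePlan"))
  if (is.null(Y)) Y <- neuralRDMVectors(tmaps, sl)
  others <- setdiff(names(theoretical), plan$target)
  if (length(others) != 2) stop("'theoretical' must contain the 3 attributes")
  set.seed(plan$seed)
  acc <- NULL
  npair <- nrow(pairIndex(8))
  for (p in seq_len(plan$n_perm)) {
    # a random scramble can collide with another predictor's bipartition
    # and make the design singular; such draws are rejected and redrawn
    for (try in seq_len(100)) {
      scr <- theoretical
      for (o in others) {
        if (plan$granularity == "labels") {
          scr[[o]] <- scrambleRDM(theoretical[[o]], sample(8))
        } else {
          v <- rdmVec(theoretical[[o]])[sample(npair)]
          m <- matrix(0, 8, 8)
          m[pairIndex(8)] <- v
          m <- m + t(m)
          scr[[o]] <- RDM(m, kind = "theoretical",
                          labels = theoretical[[o]]@labels)
        }
      }
      X <- .predictorMatrix(scr, v1)
      if (kappa(crossprod(scale(X)), exact = TRUE) < 1e10) break
      if (try == 100) stop("could not draw a non-collinear scramble")
    }
    b <- .regressAll(Y, X)[, plan$target]
    z <- if (plan$zscore == "fisher") {
      fisherZ(b)
    } else {
      (b - mean(b, na.rm = TRUE)) / stats::sd(b, na.rm = TRUE)
    }
    acc <- if (is.null(acc)) z else acc + z
  }
  vm <- VoxelMap(acc / plan$n_perm, sl@maskIdx,
                 statNames = paste0(plan$target, "_scrambled_z"),
                 dim = sl@dim)
  attr(vm, "plan") <- plan
  vm
}

#' Hierarchy analysis: Dice overlap of standard and scrambled-RSA maps
#'
#' Builds group-level corrected maps for each attribute twice -- from the
#' standard multiple-regression RSA coefficients (Fisher-transformed) and
#' from the subject-averaged scrambled z maps -- using the same sign-flip
#' Monte Carlo cluster correction, then computes the Dice coefficient
#' between the two thresholded maps.  A high DC means the attribute's map
#' barely changes when the other attributes' RDMs are scrambled, i.e. its
#' neural encoding is relatively independent of the others.
#'
#' @param standardMaps list of subject [VoxelMap-class]s from
#'   [searchlightRSA()].
#' @param scrambledMaps named list per attribute of per-subject averaged z
#'   [VoxelMap-class]s from [scrambledRSA()].
#' @param spec a [thresholdSpec()].
#' @return List: \code{dice} (data frame per attribute: n1, n2, n_common,
#'   dc), \code{standardClusters}, \code{scrambledClusters}.
#' @export
hierarchyAnalysis <- function(standardMaps, scrambledMaps,
                              spec = thresholdSpec()) {
  attrs <- names(scrambledMaps)
  maskIdx <- standardMaps[[1]]@maskIdx
  dimg <- standardMaps[[1]]@dim
  stdCl <- scrCl <- list()
  rows <- NULL
  for (a in attrs) {
    Mstd <- t(vapply(standardMaps, function(m) m@values[, a],
                     numeric(length(maskIdx))))
    csStd <- monteCarloCluster(Mstd, spec, maskIdx, dimg, fisher = TRUE)
    Mscr <- t(vapply(scrambledMaps[[a]], function(m) m@values[, 1],
                     numeric(length(maskIdx))))
    csScr <- monteCarloCluster(Mscr, spec, maskIdx, dimg, fisher = FALSE)
    d <- dice(significantVoxels(csStd), significantVoxels(csScr))
    rows <- rbind(rows, data.frame(attribute = a, n1 = d$n1, n2 = d$n2,
                                   n_common = d$n_common, dc = d$dc,
                                   both_empty = d$both_empty))
    stdCl[[a]] <- csStd
    scrCl[[a]] <- csScr
  }
  list(dice = rows, standardClusters = stdCl, scrambledClusters = scrCl)
}
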