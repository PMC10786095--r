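# Searchlight definition, RDM regression, and the searchlight
# multiple-regression RSA with group-level inference.

#' Searchlight specification
#'
#' @param k voxels per searchlight (the study uses 200; small grids
#'   typically use a proportionally smaller k).
#' @return A \code{SearchlightSpec} list.
#' @export
searchlightSpec <- function(k = 200) {
  if (k < 2) stop("'k' must be >= 2")
  structure(list(k = as.integer(k)), class = "SearchlightSpec")
}

#' Define searchlight neighborhoods on a mask
#'
#' For every in-mask voxel the k nearest in-mask voxels by Euclidean grid
#' distance, ties broken by ascending linear voxel index; each neighborhood
#' contains its center.
#'
#' @param mask logical 3D array.
#' @param spec a [searchlightSpec()] or integer k.
#' @return A [Searchlights-class].
#' @export
defineSearchlights <- function(mask, spec = searchlightSpec()) {
  k <- if (inherits(spec, "SearchlightSpec")) spec$k else as.integer(spec)
  maskIdx <- which(mask)
  V <- length(maskIdx)
  if (k > V) stop("'k' exceeds the mask size")
  co <- gridCoords(maskIdx, dim(mask))
  nb <- matrix(0L, k, V)
  chunk <- 256L
  sq <- rowSums(co^2)
  for (start in seq(1L, V, by = chunk)) {
    ix <- start:min(start + chunk - 1L, V)
    # squared distances block: |a|^2 + |b|^2 - 2 a.b
    d2 <- outer(sq[ix], sq, "+") - 2 * co[ix, , drop = FALSE] %*% t(co)
    for (r in seq_along(ix)) {
      nb[, ix[r]] <- order(d2[r, ], seq_len(V))[seq_len(k)]
    }
  }
  new("Searchlights", dim = dim(mask), maskIdx = as.integer(maskIdx),
      neighbors = nb, k = as.integer(k))
}

#' Standardized multiple regression of one RDM on predictor RDMs
#'
#' All vectors (28 pairs) are standardized to zero mean and unit variance;
#' ordinary least squares coefficients are returned in predictor order.
#'
#' @param y dependent RDM ([RDM-class] or vector of lower-triangle values).
#' @param predictors list of predictor RDMs (or vectors), or a pairs x p
#'   matrix.
#' @return Named numeric vector of standardized coefficients.
#' @export
regressRDM <- function(y, predictors) {
  yv <- if (is(y, "RDM")) rdmVec(y) else as.numeric(y)
  X <- if (is.matrix(predictors)) {
    predictors
  } else {
    vapply(predictors, function(p) if (is(p, "RDM")) rdmVec(p) else as.numeric(p),
           numeric(length(yv)))
  }
  if (stats::sd(yv) == 0) stop("dependent RDM vector has zero variance")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance predictor(s): %s",
                 paste(which(sds == 0), collapse = ", ")))
  }
  ys <- as.numeric(scale(yv))
  Xs <- scale(X)
  XtX <- crossprod(Xs)
  kap <- kappa(XtX, exact = TRUE)
  if (kap > 1e10) {
    stop(sprintf("collinear predictors (condition number %.3g)", kap))
  }
  b <- solve(XtX, crossprod(Xs, ys))
  stats::setNames(as.numeric(b), colnames(X))
}

# Predictor matrix (28 x p, standardized columns) from theoretical RDMs
# and the V1 RDM, fixed predictor order.
.predictorMatrix <- function(theoretical, v1 = NULL) {
  X <- vapply(theoretical, rdmVec, numeric(nrow(pairIndex(8))))
  if (!is.null(v1)) X <- cbind(X, v1 = rdmVec(v1))
  X
}

#' Neural RDM vectors of every searchlight
#'
#' The per-voxel dependent variables of the searchlight RSA: for each
#' center, the vectorized 1 - Pearson RDM of the 8 condition patterns over
#' its k searchlight voxels.  Searchlights containing a constant pattern
#' are skipped (NA rows, recorded in the \code{skipped} attribute).
#'
#' @param tmaps voxels x 8 condition statistic matrix (or [VoxelMap-class]).
#' @param sl a [Searchlights-class].
#' @return voxels x 28 matrix with attribute \code{skipped}.
#' @export
neuralRDMVectors <- function(tmaps, sl) {
  tm <- if (is(tmaps, "VoxelMap")) tmaps@values else as.matrix(tmaps)
  V <- ncol(sl@neighbors)
  p <- pairIndex(ncol(tm))
  Y <- matrix(NA_real_, V, nrow(p))
  skipped <- logical(V)
  for (v in seq_len(V)) {
    P <- tm[sl@neighbors[, v], ]
    if (anyNA(P)) { skipped[v] <- TRUE; next }
    s <- rowSds(t(P))
    if (any(s == 0)) { skipped[v] <- TRUE; next }
    C <- stats::cor(P)
    Y[v, ] <- 1 - C[p]
  }
  attr(Y, "skipped") <- skipped
  Y
}

# Vectorized standardized regression of every row of Y (voxels x 28) on
# the standardized predictor columns of X (28 x p).
.regressAll <- function(Y, X) {
  Xs <- scale(X)
  Ys <- standardizeRows(Y)
  B <- Ys %*% (Xs %*% solve(crossprod(Xs)))
  colnames(B) <- colnames(X)
  B
}

#' Searchlight multiple-regression RSA for one subject
#'
#' Regresses each searchlight's neural RDM on the three theoretical RDMs
#' and the V1 model RDM (all vectors standardized) and assigns each
#' predictor's coefficient to the searchlight center.
#'
#' @param tmaps the subject's condition t-maps ([VoxelMap-class] from
#'   [conditionTMaps()] or voxels x 8 matrix).
#' @param theoretical named list of three theoretical RDMs.
#' @param v1 the V1 predictor [RDM-class], or NULL to fit the 3-predictor
#'   model.
#' @param sl a [Searchlights-class].
#' @param Y optional precomputed [neuralRDMVectors()] matrix.
#' @return A [VoxelMap-class] of per-voxel coefficients, one statistic per
#'   predictor; skipped searchlights are NA.
#' @export
searchlightRSA <- function(tmaps, theoretical, v1, sl, Y = NULL) {
  if (is.null(Y)) Y <- neuralRDMVectors(tmaps, sl)
  X <- .predictorMatrix(theoretical, v1)
  B <- .regressAll(Y, X)
  out <- VoxelMap(B, sl@maskIdx, statNames = colnames(X), dim = sl@dim)
  attr(out, "skipped") <- attr(Y, "skipped")
  out
}

#' Group-level inference on subject RSA maps
#'
#' Fisher-transforms each subject's coefficient maps (atanh with inputs
#' clipped to +/- 0.999) and computes a voxel-wise one-sample t-test
#' against zero per predictor.  Voxels with zero between-subject variance
#' are capped at |t| = 100 and flagged.
#'
#' @param maps list of subject [VoxelMap-class]s (same grid and
#'   statistics).
#' @param fisher apply the Fisher transform before testing (default TRUE;
#'   set FALSE for inputs that are already z-scale, e.g. scrambled-RSA
#'   averaged z maps).
#' @return Named list per predictor of [VoxelMap-class]s with statistics
#'   \code{t}, \code{mean} and \code{p} (one-sided, positive direction);
#'   attribute \code{df}.
#' @export
groupRSA <- function(maps, fisher = TRUE) {
  stopifnot(length(maps) >= 2)
  stats_ <- maps[[1]]@statNames
  n <- length(maps)
  out <- lapply(stats_, function(sn) {
    M <- vapply(maps, function(m) m@values[, sn], numeric(nrow(maps[[1]]@values)))
    M <- t(M)                       # subjects x voxels
    if (fisher) M <- fisherZ(M)
    ok <- colSums(is.na(M)) == 0
    tt <- rep(NA_real_, ncol(M))
    mm <- rep(NA_real_, ncol(M))
    res <- colOneSampleT(M[, ok, drop = FALSE])
    tt[ok] <- res$t
    mm[ok] <- res$mean
    p <- stats::pt(tt, df = n - 1, lower.tail = FALSE)
    vm <- VoxelMap(cbind(t = tt, mean = mm, p = p), maps[[1]]@maskIdx,
                   dim = maps[[1]]@dim)
    attr(vm, "df") <- n - 1L
    vm
  })
  names(out) <- stats_
  out
}
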