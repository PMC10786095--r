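# Run-wise GLM estimation: per-run condition betas for MVPA and pooled
# condition t-maps (concatenated runs, run-wise intercepts and nuisance
# regressors) for RSA.

#' Build a run's design matrix
#'
#' Columns: 8 HRF-convolved stimulus boxcar regressors (peak-normalized),
#' the 6 nuisance regressors, an intercept, and optionally two low-frequency
#' drift terms (linear + half-cosine).
#'
#' @param timeline a \code{Timeline}.
#' @param nuisance volumes x 6 nuisance matrix.
#' @param stimulus_ids character(8) condition order of the stimulus columns.
#' @param drift include drift regressors (default TRUE).
#' @return Design matrix (volumes x columns) with column names; attribute
#'   \code{stimCols} marks the stimulus columns.
#' @export
makeDesignMatrix <- function(timeline, nuisance, stimulus_ids, drift = TRUE) {
  nvol <- attr(timeline, "n_volumes")
  tr <- attr(timeline, "tr")
  if (!is.null(nuisance) && nrow(nuisance) != nvol) {
    stop("nuisance regressors must have one row per volume")
  }
  X <- vapply(stimulus_ids, function(id) {
    ev <- timeline[timeline$trial_type == id, , drop = FALSE]
    if (!nrow(ev)) return(numeric(nvol))
    hrfRegressor(ev$onset, ev$duration, tr, nvol)
  }, numeric(nvol))
  colnames(X) <- stimulus_ids
  if (!is.null(nuisance)) X <- cbind(X, nuisance)
  X <- cbind(X, intercept = 1)
  if (drift) {
    tt <- (seq_len(nvol) - 1) / (nvol - 1) - 0.5
    X <- cbind(X, drift_lin = tt, drift_cos = cos(pi * (tt + 0.5)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear or empty columns: %s",
                 paste(dropped, collapse = ", ")))
  }
  structure(X, stimCols = seq_along(stimulus_ids))
}

#' Fit a per-run voxel-wise GLM
#'
#' Ordinary least squares per voxel; returns the 8 stimulus betas in
#' stimulus order plus residual statistics.
#'
#' @param series volumes x voxels matrix (in-mask voxels).
#' @param X design matrix from [makeDesignMatrix()].
#' @return List: \code{betas} (8 x voxels stimulus betas), \code{coef}
#'   (all columns), \code{resvar}, \code{dof}.
#' @export
fitRunGLM <- function(series, X) {
  if (!all(is.finite(series))) stop("'series' contains non-finite values")
  if (nrow(series) != nrow(X)) stop("series/design row mismatch")
  qrX <- qr(X)
  coef <- qr.coef(qrX, series)
  res <- series - X %*% coef
  dof <- nrow(X) - qrX$rank
  resvar <- colSums(res^2) / dof
  stim <- attr(X, "stimCols")
  list(betas = coef[stim, , drop = FALSE], coef = coef,
       resvar = resvar, dof = dof)
}

#' Pooled condition t-maps from all runs
#'
#' Runs are concatenated with shared stimulus regressors and run-wise
#' intercept, nuisance and drift columns; t = beta / SE(beta) per condition
#' per voxel.  Voxels with zero residual variance get NA t with a warning.
#'
#' @param subject a [SubjectData-class], or a list of series matrices.
#' @param stimulus_ids condition order; defaults to the subject's labels.
#' @param drift include run-wise drift regressors.
#' @return A [VoxelMap-class] with the 8 t statistics, plus attributes
#'   \code{betas} (voxels x 8) and \code{dof}.
#' @export
conditionTMaps <- function(subject, stimulus_ids = NULL, drift = TRUE) {
  stopifnot(is(subject, "SubjectData"))
  if (is.null(stimulus_ids)) stimulus_ids <- subject@labels$id
  nr <- length(subject@runs)
  if (nr < 2) stop("need at least 2 runs")
  Xs <- Ys <- vector("list", nr)
  for (r in seq_len(nr)) {
    Xr <- makeDesignMatrix(subject@timelines[[r]], subject@nuisance[[r]],
                           stimulus_ids, drift = drift)
    Xs[[r]] <- Xr
    Ys[[r]] <- subject@runs[[r]]
  }
  nvol <- vapply(Xs, nrow, 0L)
  stim <- attr(Xs[[1]], "stimCols")
  pRun <- ncol(Xs[[1]]) - length(stim)
  bigX <- matrix(0, sum(nvol), length(stim) + nr * pRun)
  rowOff <- 0
  for (r in seq_len(nr)) {
    rows <- rowOff + seq_len(nvol[r])
    bigX[rows, seq_along(stim)] <- Xs[[r]][, stim]
    cols <- length(stim) + (r - 1) * pRun + seq_len(pRun)
    bigX[rows, cols] <- Xs[[r]][, -stim]
    rowOff <- rowOff + nvol[r]
  }
  colnames(bigX) <- c(stimulus_ids,
                      as.vector(vapply(seq_len(nr), function(r) {
                        paste0("run", r, "_", colnames(Xs[[1]])[-stim])
                      }, character(pRun))))
  Y <- do.call(rbind, Ys)
  qrX <- qr(bigX)
  if (qrX$rank < ncol(bigX)) stop("concatenated design is rank deficient")
  coef <- qr.coef(qrX, Y)
  res <- Y - bigX %*% coef
  dof <- nrow(bigX) - qrX$rank
  resvar <- colSums(res^2) / dof
  xtxinv <- chol2inv(chol(crossprod(bigX)))
  se2 <- diag(xtxinv)[seq_along(stim)]
  betas <- t(coef[seq_along(stim), , drop = FALSE])
  tmat <- betas / sqrt(outer(resvar, se2))
  if (any(resvar == 0)) {
    warning(sprintf("%d voxels with zero residual variance: t undefined",
                    sum(resvar == 0)))
    tmat[resvar == 0, ] <- NA_real_
  }
  colnames(tmat) <- stimulus_ids
  out <- VoxelMap(tmat, subject@mask, statNames = stimulus_ids)
  attr(out, "betas") <- betas
  attr(out, "dof") <- dof
  out
}

#' Per-run stimulus betas for MVPA
#'
#' Fits each run's GLM separately and collects the 8 x n_runs beta
#' patterns.
#'
#' @param subject a [SubjectData-class].
#' @param drift include drift regressors.
#' @return List: \code{betas} voxels x (8 * n_runs) matrix (condition fast,
#'   run slow), \code{condition}, \code{run} label vectors.
#' @export
runBetas <- function(subject, drift = TRUE) {
  stopifnot(is(subject, "SubjectData"))
  ids <- subject@labels$id
  nr <- length(subject@runs)
  out <- vector("list", nr)
  for (r in seq_len(nr)) {
    X <- makeDesignMatrix(subject@timelines[[r]], subject@nuisance[[r]],
                          ids, drift = drift)
    out[[r]] <- t(fitRunGLM(subject@runs[[r]], X)$betas)
  }
  betas <- do.call(cbind, out)
  colnames(betas) <- paste(rep(ids, nr), rep(seq_len(nr), each = 8), sep = "_run")
  list(betas = betas, condition = rep(ids, nr), run = rep(seq_len(nr), each = 8))
}
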