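# Synthetic BOLD generator with planted, controllable attribute structure.
#
# The generator emulates the study's acquisition (6 runs x 24 12-s blocks
# interleaved with 6-s fixations, TR 2 s, 219 volumes/run) on a small voxel
# grid.  Three disjoint ROIs carry multivoxel codes for facing direction,
# gender and emotional state: every ROI voxel responds to its attribute's
# category sign through a voxel-specific tuning gain, which is what makes
# the planted structure visible to pattern correlation (RSA) and decoding
# (MVPA) rather than only to the mean response.

#' Default signed category codes of the 8 stimuli
#'
#' +1 for right-facing, male, happy; -1 for left-facing, female, sad.
#'
#' @param labels stimulus label data frame (columns facing, gender, emotion).
#' @return 8 x 3 sign matrix with columns facing, gender, emotion.
#' @export
attributeSigns <- function(labels) {
  cbind(facing = ifelse(labels$facing == "right", 1, -1),
        gender = ifelse(labels$gender == "male", 1, -1),
        emotion = ifelse(labels$emotion == "happy", 1, -1))
}

#' Gray-matter analog tissue probability map
#'
#' Radial Gaussian probability centered on the grid; thresholding at 0.2
#' yields an approximately spherical mask of radius ~0.47 N.
#'
#' @param dim integer(3) grid dimensions.
#' @return Numeric 3D array in [0, 1].
#' @export
tissueProbability <- function(dim) {
  ctr <- (dim + 1) / 2
  sig <- 0.265 * mean(dim)
  co <- gridCoords(seq_len(prod(dim)), dim)
  r2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
  array(exp(-r2 / (2 * sig^2)), dim)
}

#' Default planted regions of interest
#'
#' Three disjoint balls (radius 0.165 N) inside the default mask, one per
#' attribute.
#'
#' @param dim integer(3) grid dimensions.
#' @return Named list of linear voxel index vectors
#'   (facing, gender, emotion).
#' @export
defaultROIs <- function(dim = c(20, 20, 20)) {
  N <- dim
  r <- 0.165 * N[1]
  co <- gridCoords(seq_len(prod(N)), N)
  ball <- function(cf) {
    ctr <- cf * N
    d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
    which(d2 <= r^2)
  }
  list(facing = ball(c(0.325, 0.525, 0.525)),
       gender = ball(c(0.725, 0.525, 0.525)),
       emotion = ball(c(0.525, 0.525, 0.8)))
}

#' Effect specification for the synthetic group
#'
#' @param grid_shape integer(3) voxel grid.
#' @param rois named list of linear voxel indices per attribute; defaults
#'   to [defaultROIs()].  ROIs must lie inside the mask.
#' @param effect_size named amplitudes (peak percent signal) per attribute.
#' @param interaction named numeric of cross-attribute couplings.  Names of
#'   the form \code{"target:source"} plant additive source-attribute signed
#'   structure into ROI_target (the target region also encodes the source
#'   attribute); names of the form \code{"target*source"} plant a
#'   product-signed modulation (the target attribute's contrast magnitude
#'   depends on the source category).
#' @param tuning_sd SD of the per-voxel tuning gain around 1 (the gain
#'   multiplies the attribute effect and gives each ROI voxel its own
#'   preference strength).
#' @param idiosyncratic_sd SD of per-voxel, per-stimulus amplitude jitter
#'   inside ROIs.
#' @param noise_sd marginal SD of the AR(1) scanner noise (percent signal
#'   units, baseline 100).
#' @param ar1 lag-1 autocorrelation of the noise, in [0, 1).
#' @param drift SD of per-voxel low-frequency (linear + half-cosine) drift
#'   weights.
#' @param nuisance_coupling SD of per-voxel weights on the synthetic motion
#'   regressors.
#' @param evoked_baseline common stimulus-evoked amplitude added everywhere
#'   in the mask.
#' @param mask_threshold tissue probability threshold (0.2).
#' @param seed integer seed used for the planted truth.
#' @return An \code{EffectSpec} list.
#' @export
effectSpec <- function(grid_shape = c(20, 20, 20), rois = NULL,
                       effect_size = c(facing = 1, gender = 1, emotion = 1),
                       interaction = numeric(0),
                       tuning_sd = 0.5, idiosyncratic_sd = 0.3,
                       noise_sd = 11, ar1 = 0.3, drift = 0.5,
                       nuisance_coupling = 0.1, evoked_baseline = 1,
                       mask_threshold = 0.2, seed = 1) {
  if (ar1 < 0 || ar1 >= 1) stop("'ar1' must be in [0, 1)")
  stopifnot(all(is.finite(effect_size)))
  if (is.null(rois)) rois <- defaultROIs(grid_shape)
  structure(list(grid_shape = as.integer(grid_shape), rois = rois,
                 effect_size = effect_size, interaction = interaction,
                 tuning_sd = tuning_sd, idiosyncratic_sd = idiosyncratic_sd,
                 noise_sd = noise_sd, ar1 = ar1, drift = drift,
                 nuisance_coupling = nuisance_coupling,
                 evoked_baseline = evoked_baseline,
                 mask_threshold = mask_threshold, seed = as.integer(seed)),
            class = "EffectSpec")
}

#' Plant per-voxel, per-stimulus true amplitudes
#'
#' amplitude(v, s) = evoked_baseline
#'   + sum over attributes a with v in ROI_a of
#'       effect_size[a] * sign_a(s) * gain(v, a)
#'   + sum over couplings target:source with v in ROI_target of
#'       interaction * sign_source(s) * gain(v, pair)
#'   + idiosyncratic jitter(v, s) inside ROIs,
#' with gain(v, .) = 1 + tuning_sd * N(0,1), all draws seeded.
#'
#' @param effects an [effectSpec()].
#' @param labels stimulus label data frame (8 rows).
#' @param combine how to treat overlapping ROIs: \code{"error"} (default)
#'   or \code{"additive"}.
#' @return List: \code{truth} (mask voxels x 8 amplitude matrix),
#'   \code{mask}, \code{tissueProb}, \code{roiIdx} (per-attribute indices
#'   into the mask-voxel ordering), \code{signs}.
#' @export
plantAmplitudes <- function(effects, labels, combine = c("error", "additive")) {
  combine <- match.arg(combine)
  dimg <- effects$grid_shape
  tp <- tissueProbability(dimg)
  mask <- tp > effects$mask_threshold
  maskIdx <- which(mask)
  V <- length(maskIdx)
  lut <- integer(prod(dimg))
  lut[maskIdx] <- seq_len(V)
  roiIdx <- lapply(effects$rois, function(ix) {
    if (!all(mask[ix])) stop("ROI voxels must lie inside the mask")
    lut[ix]
  })
  if (combine == "error" && length(roiIdx) > 1) {
    all_ix <- unlist(roiIdx)
    if (anyDuplicated(all_ix)) {
      stop("ROIs overlap; pass combine = 'additive' to sum their effects")
    }
  }
  signs <- attributeSigns(labels)
  set.seed(deriveSeed(effects$seed, "truth"))
  truth <- matrix(effects$evoked_baseline, V, 8,
                  dimnames = list(NULL, labels$id))
  for (a in names(effects$effect_size)) {
    ix <- roiIdx[[a]]
    if (is.null(ix) || !length(ix)) next
    es <- effects$effect_size[[a]]
    gain <- 1 + effects$tuning_sd * stats::rnorm(length(ix))
    truth[ix, ] <- truth[ix, ] + es * outer(gain, signs[, a])
  }
  if (length(effects$interaction)) {
    for (nm in names(effects$interaction)) {
      mult <- grepl("*", nm, fixed = TRUE)
      parts <- strsplit(nm, if (mult) "*" else ":", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("interaction names must be 'target:source' or 'target*source'")
      }
      ix <- roiIdx[[parts[1]]]
      if (is.null(ix)) stop(sprintf("unknown interaction target '%s'", parts[1]))
      amp <- effects$interaction[[nm]]
      gain <- 1 + effects$tuning_sd * stats::rnorm(length(ix))
      code <- if (mult) signs[, parts[1]] * signs[, parts[2]] else signs[, parts[2]]
      truth[ix, ] <- truth[ix, ] + amp * outer(gain, code)
    }
  }
  if (effects$idiosyncratic_sd > 0) {
    inROI <- sort(unique(unlist(roiIdx)))
    if (length(inROI)) {
      truth[inROI, ] <- truth[inROI, ] +
        effects$idiosyncratic_sd * matrix(stats::rnorm(length(inROI) * 8),
                                          length(inROI), 8)
    }
  }
  list(truth = truth, mask = mask, tissueProb = tp, roiIdx = roiIdx,
       signs = signs)
}

# Synthetic head-motion nuisance regressors: slow random walks.
.makeNuisance <- function(n_volumes, seed) {
  set.seed(seed)
  m <- apply(matrix(stats::rnorm(n_volumes * 6, sd = 0.02), n_volumes, 6),
             2, cumsum)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate one run of BOLD data
#'
#' Expected signal at voxel v is \code{rest + sum_s truth(v, s) * x_s(t)}
#' with x_s the HRF-convolved boxcar of stimulus s (peak-normalized), plus
#' AR(1) Gaussian noise, per-voxel low-frequency drift and a component
#' correlated with the nuisance regressors.
#'
#' @param timeline a \code{Timeline} from [buildTimeline()].
#' @param truth mask voxels x 8 amplitude matrix.
#' @param effects an [effectSpec()].
#' @param nuisance volumes x 6 nuisance regressor matrix.
#' @param seed integer noise seed.
#' @param rest resting-state signal level (default 100, so amplitudes are
#'   percent signal).
#' @return volumes x voxels numeric matrix.
#' @export
simulateRun <- function(timeline, truth, effects, nuisance, seed,
                        rest = 100) {
  nvol <- attr(timeline, "n_volumes")
  tr <- attr(timeline, "tr")
  ids <- colnames(truth)
  X <- vapply(ids, function(id) {
    ev <- timeline[timeline$trial_type == id, , drop = FALSE]
    if (!nrow(ev)) return(numeric(nvol))
    hrfRegressor(ev$onset, ev$duration, tr, nvol)
  }, numeric(nvol))
  signal <- rest + X %*% t(truth)
  V <- nrow(truth)
  set.seed(seed)
  if (effects$noise_sd > 0) {
    innov_sd <- effects$noise_sd * sqrt(1 - effects$ar1^2)
    noise <- matrix(0, nvol, V)
    noise[1, ] <- stats::rnorm(V, sd = effects$noise_sd)
    for (t in 2:nvol) {
      noise[t, ] <- effects$ar1 * noise[t - 1, ] +
        stats::rnorm(V, sd = innov_sd)
    }
    signal <- signal + noise
  }
  if (effects$drift > 0) {
    tt <- (seq_len(nvol) - 1) / (nvol - 1) - 0.5
    basis <- cbind(tt, cos(pi * (tt + 0.5)))
    w <- matrix(stats::rnorm(2 * V, sd = effects$drift), 2, V)
    signal <- signal + basis %*% w
  }
  if (effects$nuisance_coupling > 0) {
    w <- matrix(stats::rnorm(6 * V, sd = effects$nuisance_coupling), 6, V)
    signal <- signal + nuisance %*% w
  }
  signal
}

#' Simulate a complete synthetic participant
#'
#' Plants the per-subject truth (subject-specific tuning gains on shared
#' ROI geometry), then simulates all runs with seeded block orders,
#' nuisance regressors and noise.
#'
#' @param design a [designSpec()].
#' @param effects an [effectSpec()].
#' @param labels stimulus label data frame; defaults to the standard
#'   8-stimulus crossing.
#' @param seed integer subject seed; every random component is derived
#'   from it.
#' @return A [SubjectData-class] object.
#' @export
simulateSubject <- function(design = designSpec(), effects = effectSpec(),
                            labels = NULL, seed = 1) {
  if (is.null(labels)) labels <- stimulusLabels()
  eff <- effects
  eff$seed <- deriveSeed(seed, "subject-truth")
  planted <- plantAmplitudes(eff, labels)
  nvol <- NULL
  runs <- timelines <- nuis <- vector("list", design$n_runs)
  for (r in seq_len(design$n_runs)) {
    tl <- buildTimeline(design, labels$id, seed = deriveSeed(seed, "timeline", r))
    nv <- attr(tl, "n_volumes")
    nu <- .makeNuisance(nv, deriveSeed(seed, "nuisance", r))
    runs[[r]] <- simulateRun(tl, planted$truth, effects, nu,
                             seed = deriveSeed(seed, "noise", r))
    timelines[[r]] <- tl
    nuis[[r]] <- nu
  }
  new("SubjectData", runs = runs, timelines = timelines, nuisance = nuis,
      mask = planted$mask, tissueProb = planted$tissueProb,
      truth = planted$truth, effects = unclass(effects),
      design = unclass(design), labels = labels, seed = as.integer(seed))
}

#' Simulate a group of participants
#'
#' @param n_subjects number of participants (default 20, the analyzed
#'   sample size the synthetic group mirrors).
#' @param design,effects,labels as in [simulateSubject()].
#' @param base_seed integer; subject s uses a seed derived from it.
#' @return List of [SubjectData-class] objects.
#' @export
simulateGroup <- function(n_subjects = 20, design = designSpec(),
                          effects = effectSpec(), labels = NULL,
                          base_seed = 1) {
  if (n_subjects < 2) stop("'n_subjects' must be >= 2")
  lapply(seq_len(n_subjects), function(s) {
    simulateSubject(design, effects, labels,
                    seed = deriveSeed(base_seed, "group-subject", s))
  })
}

#' The standard 8-stimulus label table
#'
#' @return Data frame with columns id, facing, gender, emotion (8 rows,
#'   the full 2 x 2 x 2 crossing).
#' @export
stimulusLabels <- function() {
  buildStimulusSet(n_frames = 2, render = FALSE)$labels
}

#' Simulate the 96-trial behavioral rating table
#'
#' Each of the 8 stimuli is rated on each of the 3 attributes 4 times on a
#' 1--7 semantic differential scale:
#' rating = clamp(round(4 + slope * sign + criterion noise), 1, 7).
#'
#' @param labels stimulus label data frame.
#' @param slope response slope toward the stimulus's true category
#'   (scale points per signed category unit).
#' @param criterion_sd SD of Gaussian criterion noise.
#' @param seed integer seed.
#' @return A \code{RatingTable} data frame with 96 rows: stimulus_id,
#'   attribute, repetition, rating.
#' @export
simulateRatings <- function(labels = stimulusLabels(), slope = 1.5,
                            criterion_sd = 1, seed = 1) {
  signs <- attributeSigns(labels)
  set.seed(seed)
  rows <- expand.grid(repetition = 1:4, stimulus_id = labels$id,
                      attribute = colnames(signs),
                      stringsAsFactors = FALSE)[, c(2, 3, 1)]
  s <- signs[cbind(match(rows$stimulus_id, labels$id),
                   match(rows$attribute, colnames(signs)))]
  raw <- 4 + slope * s + stats::rnorm(nrow(rows), sd = criterion_sd)
  rows$rating <- as.integer(clamp(round(raw), 1, 7))
  class(rows) <- c("RatingTable", "data.frame")
  rows
}

#' Flag participants by behavioral exclusion criteria
#'
#' Utility mirroring the study's exclusion rules on rating tables:
#' (i) a subject's mean rating for some attribute lies outside three group
#' SDs, or (ii) more than 50% "4 - not sure" responses for some attribute.
#'
#' @param tables list of \code{RatingTable}s, one per subject.
#' @return Logical vector: TRUE = excluded.
#' @export
ratingExclusionFlags <- function(tables) {
  attrs <- unique(tables[[1]]$attribute)
  meansMat <- t(vapply(tables, function(tb) {
    vapply(attrs, function(a) mean(tb$rating[tb$attribute == a]), 0)
  }, numeric(length(attrs))))
  mu <- colMeans(meansMat)
  sdv <- apply(meansMat, 2, stats::sd)
  outlier <- rowSums(t(abs(t(meansMat) - mu) > 3 * pmax(sdv, 1e-12))) > 0
  unsure <- vapply(tables, function(tb) {
    any(vapply(attrs, function(a) {
      mean(tb$rating[tb$attribute == a] == 4) > 0.5
    }, NA))
  }, NA)
  outlier | unsure
}
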