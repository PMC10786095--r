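# RDM construction and vectorization.

#' Lower-triangle pair index table
#'
#' Fixed row-major lower-triangle ordering used for every RDM vector in an
#' analysis: (2,1), (3,1), (3,2), (4,1), ... For 8 conditions this gives
#' the 28 condition pairs.
#'
#' @param n number of conditions.
#' @return Integer matrix with columns \code{i}, \code{j} (i > j).
#' @export
pairIndex <- function(n = 8) {
  i <- unlist(lapply(2:n, function(r) rep(r, r - 1)))
  j <- unlist(lapply(2:n, function(r) seq_len(r - 1)))
  cbind(i = i, j = j)
}

#' Vectorize an RDM
#'
#' Extracts the lower triangle in the fixed row-major pair order of
#' [pairIndex()].
#'
#' @param rdm an [RDM-class] or square matrix.
#' @return Numeric vector of length n(n-1)/2 (28 for 8 conditions).
#' @export
rdmVec <- function(rdm) {
  v <- if (is(rdm, "RDM")) rdm@values else as.matrix(rdm)
  p <- pairIndex(nrow(v))
  v[p]
}

#' Theoretical attribute RDMs
#'
#' One binary RDM per attribute: 1 for between-category pairs, 0 for
#' within-category pairs.  With the balanced 2x2x2 stimulus crossing each
#' RDM has 16 between and 12 within off-diagonal pairs, and any two
#' attribute RDM vectors correlate at exactly -1/6.
#'
#' @param labels stimulus label data frame (columns facing, gender,
#'   emotion), the full balanced crossing.
#' @return Named list of three theoretical [RDM-class]s.
#' @export
theoreticalRDMs <- function(labels = stimulusLabels()) {
  attrs <- c("facing", "gender", "emotion")
  out <- lapply(attrs, function(a) {
    cat_ <- labels[[a]]
    if (length(unique(cat_)) != 2 || length(cat_) != 8 ||
        sum(cat_ == cat_[1]) != 4) {
      stop(sprintf("attribute '%s' must split the 8 stimuli 4/4", a))
    }
    m <- outer(cat_, cat_, FUN = "!=") * 1
    diag(m) <- 0
    RDM(m, kind = "theoretical", labels = labels$id)
  })
  names(out) <- attrs
  out
}

#' Neural RDM of a multivoxel pattern set
#'
#' 1 - Pearson correlation between the condition patterns (correlation
#' taken across voxels).
#'
#' @param patterns voxels x conditions numeric matrix.
#' @param labels condition labels.
#' @return An [RDM-class] of kind \code{"neural"}, entries in [0, 2].
#' @export
neuralRDM <- function(patterns, labels = colnames(patterns)) {
  patterns <- as.matrix(patterns)
  if (any(apply(patterns, 2, stats::sd) == 0)) {
    stop("constant pattern: correlation undefined")
  }
  d <- 1 - stats::cor(patterns)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(patterns)))
  RDM(d, kind = "neural", labels = labels)
}

#' Scramble an RDM by condition relabeling
#'
#' Jointly permutes rows and columns, preserving symmetry, the zero
#' diagonal, and the multiset of off-diagonal values.
#'
#' @param rdm an [RDM-class].
#' @param perm integer permutation of the conditions.
#' @return The permuted [RDM-class] (labels keep their positions).
#' @export
scrambleRDM <- function(rdm, perm) {
  stopifnot(is(rdm, "RDM"))
  n <- nrow(rdm@values)
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    stop("'perm' must be a permutation of the condition indices")
  }
  RDM(rdm@values[perm, perm], kind = rdm@kind, labels = rdm@labels)
}

#' Behavioral RDM from a rating table
#'
#' Mean rating per stimulus over its repetitions for one attribute;
#' dissimilarity is the Euclidean distance between the (scalar) means,
#' i.e. the absolute difference.
#'
#' @param ratings a \code{RatingTable} from [simulateRatings()].
#' @param attribute one of facing, gender, emotion.
#' @param labels stimulus label data frame fixing the condition order.
#' @return An [RDM-class] of kind \code{"behavioral"}.
#' @export
behavioralRDM <- function(ratings, attribute, labels = stimulusLabels()) {
  tb <- ratings[ratings$attribute == attribute, , drop = FALSE]
  counts <- table(factor(tb$stimulus_id, levels = labels$id))
  if (any(counts < 1)) {
    stop(sprintf("missing repetitions for stimuli: %s",
                 paste(names(counts)[counts < 1], collapse = ", ")))
  }
  m <- vapply(labels$id, function(id) mean(tb$rating[tb$stimulus_id == id]), 0)
  d <- abs(outer(m, m, "-"))
  RDM(d, kind = "behavioral", labels = labels$id)
}
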