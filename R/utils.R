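# Small internal helpers shared across modules.

#' Derive a stage seed from a global seed
#'
#' Deterministic mapping from one global integer seed plus a stage label
#' (and optional index) to a stage-specific seed, kept below 2^31 so it
#' remains a valid R integer.  All of the package's stochastic stages are
#' seeded through this derivation.
#'
#' @param seed global integer seed.
#' @param label stage label (any string).
#' @param i optional unit index (e.g. subject number).
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, label, i = 0L) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 1000003 + i * 7919) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Row standard deviations without matrixStats.
rowSds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(pmax(rowSums(x * x) - n * m * m, 0) / (n - 1))
}

# Standardize matrix rows to mean 0, sd 1 (rows with sd 0 become NA).
standardizeRows <- function(x) {
  m <- rowMeans(x)
  s <- rowSds(x)
  s[s == 0] <- NA_real_
  (x - m) / s
}

standardizeCols <- function(x) {
  t(standardizeRows(t(x)))
}

# Integer (i, j, k) coordinates of linear indices on a 3D grid.
gridCoords <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

# Fisher z-transform with clipping so atanh stays finite on |r| near 1.
fisherZ <- function(r, clip = 0.999) {
  atanh(clamp(r, -clip, clip))
}

# One-sample t over columns of a subjects x voxels matrix (vs mu).
# Returns list(t, df, mean, sd). Zero-variance columns get t = sign * cap.
colOneSampleT <- function(x, mu = 0, cap = 100) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt(pmax(colSums(x * x) - n * m * m, 0) / (n - 1))
  t <- (m - mu) / (s / sqrt(n))
  zero <- s == 0
  if (any(zero)) t[zero] <- sign(m[zero] - mu) * cap
  list(t = t, df = n - 1L, mean = m, sd = s, zeroVar = zero)
}

# Separable 3D Gaussian smoothing (used to build spatially correlated
# null fields resembling searchlight maps).
gaussianSmooth3D <- function(arr, sigma = 1.5) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(-r:r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  sm1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    as.numeric(stats::filter(xp, kern, sides = 2))[(r + 1):(r + n)]
  }
  d <- dim(arr)
  out <- apply(arr, c(2, 3), sm1)
  out <- aperm(apply(out, c(1, 3), sm1), c(2, 1, 3))
  aperm(apply(out, c(1, 2), sm1), c(2, 3, 1))
}

#' Generate spatially smooth Gaussian random fields
#'
#' White Gaussian noise filtered with an isotropic Gaussian kernel in
#' Fourier space (circular boundary), each field rescaled to zero mean and
#' unit variance.  Used as a spatially correlated null model resembling
#' searchlight statistic maps.
#'
#' @param dim integer(3) grid dimensions.
#' @param sigma kernel SD in voxels.
#' @param n number of fields.
#' @param seed integer seed.
#' @return List of n 3D arrays.
#' @export
smoothGaussianField <- function(dim, sigma = 2, n = 1, seed = 1) {
  ax <- lapply(dim, function(d) {
    x <- c(0:(d %/% 2), -((d - d %/% 2 - 1):1))
    x^2
  })
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  K <- stats::fft(exp(-d2 / (2 * sigma^2)))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    z <- array(stats::rnorm(prod(dim)), dim)
    f <- Re(stats::fft(stats::fft(z) * K, inverse = TRUE)) / prod(dim)
    (f - mean(f)) / stats::sd(f)
  })
}
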