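# HMAX S1/C1 approximation of early visual (V1) responses.
#
# S1: normalized absolute correlation of the image with a bank of zero-mean,
# unit-norm Gabor filters (4 orientations x 8 sizes grouped into 4 scale
# bands).  C1: local maximum pooling over space (half-overlapping cells)
# and over the two filter sizes within each band.  Per-frame C1 vectors are
# averaged over frames to give one feature vector per stimulus, and the V1
# predictor RDM is 1 - Pearson correlation between stimulus features.

#' Gabor filter bank for the S1 stage
#'
#' Standard C1 parameterization: filter sizes 7--21 px in four two-size
#' bands, pool sizes 8--14 px with half-overlap, four orientations.  Each
#' filter is zero-mean and unit-norm.
#'
#' @param orientations orientation angles in degrees (>= 2 required).
#' @param sizes filter side lengths in pixels (even count; consecutive
#'   pairs form scale bands).
#' @param poolSizes C1 pooling cell size per band.
#' @param gamma Gabor aspect ratio.
#' @return A \code{GaborBank} list with \code{filters[[size]][[orientation]]}.
#' @export
gaborBank <- function(orientations = c(0, 45, 90, 135),
                      sizes = c(7, 9, 11, 13, 15, 17, 19, 21),
                      poolSizes = c(8, 10, 12, 14),
                      gamma = 0.3) {
  if (length(orientations) < 2) stop("need at least 2 orientations")
  if (length(sizes) %% 2 != 0) stop("'sizes' must pair into bands")
  if (length(poolSizes) != length(sizes) / 2) {
    stop("one pool size per band required")
  }
  filters <- lapply(sizes, function(s) {
    sigma <- 0.0036 * s^2 + 0.35 * s - 0.18
    lambda <- sigma / 0.8
    half <- (s - 1) / 2
    xy <- seq(-half, half)
    lapply(orientations, function(th) {
      # 'th' is the preferred stimulus orientation; the carrier runs
      # perpendicular to it
      a <- (th + 90) * pi / 180
      X <- outer(xy, xy, function(y, x) x * cos(a) + y * sin(a))
      Y <- outer(xy, xy, function(y, x) -x * sin(a) + y * cos(a))
      g <- exp(-(X^2 + gamma^2 * Y^2) / (2 * sigma^2)) * cos(2 * pi * X / lambda)
      g[sqrt(X^2 + Y^2) > half] <- 0
      g <- g - mean(g)
      g / sqrt(sum(g^2))
    })
  })
  names(filters) <- paste0("s", sizes)
  structure(list(orientations = orientations, sizes = sizes,
                 poolSizes = poolSizes, nBands = length(poolSizes),
                 filters = filters),
            class = "GaborBank")
}

# FFT-based 2D convolution, 'same' output, zero padding.
.conv2same <- function(A, kernelFFT, padDim, kdim) {
  pa <- matrix(0, padDim[1], padDim[2])
  pa[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  full <- Re(stats::fft(stats::fft(pa) * kernelFFT, inverse = TRUE)) /
    prod(padDim)
  r0 <- (kdim[1] - 1) %/% 2
  c0 <- (kdim[2] - 1) %/% 2
  full[r0 + seq_len(nrow(A)), c0 + seq_len(ncol(A)), drop = FALSE]
}

.padFFT <- function(K, padDim) {
  pk <- matrix(0, padDim[1], padDim[2])
  pk[seq_len(nrow(K)), seq_len(ncol(K))] <- K
  stats::fft(pk)
}

# Precompute kernel FFTs (filters + norm kernels) for one image size.
.s1Prepare <- function(dims, bank) {
  prep <- list()
  for (si in seq_along(bank$sizes)) {
    s <- bank$sizes[si]
    if (s > min(dims)) {
      stop(sprintf("frame (%dx%d) smaller than the %d-px filter",
                   dims[1], dims[2], s))
    }
    padDim <- dims + s - 1
    kf <- lapply(bank$filters[[si]], .padFFT, padDim = padDim)
    nf <- .padFFT(matrix(1, s, s), padDim)
    prep[[si]] <- list(size = s, padDim = padDim, kernels = kf, norm = nf)
  }
  prep
}

.s1Apply <- function(frame, bank, prep) {
  out <- vector("list", length(bank$sizes))
  f2 <- frame^2
  dims <- dim(frame)
  for (si in seq_along(bank$sizes)) {
    p <- prep[[si]]
    kdim <- c(p$size, p$size)
    half <- (p$size - 1) %/% 2
    den <- .conv2same(f2, p$norm, p$padDim, kdim)
    den <- pmax(sqrt(pmax(den, 0)), 1e-6)
    maps <- lapply(p$kernels, function(kf) {
      num <- .conv2same(frame, kf, p$padDim, kdim)
      r <- pmin(abs(num) / den, 1)
      # zero the border band where the filter support leaves the image
      r[c(seq_len(half), dims[1] - seq_len(half) + 1), ] <- 0
      r[, c(seq_len(half), dims[2] - seq_len(half) + 1)] <- 0
      r
    })
    out[[si]] <- maps
  }
  names(out) <- names(bank$filters)
  out
}

#' S1 stage: Gabor responses of one frame
#'
#' Returns rectified, locally normalized responses in [0, 1]: the absolute
#' correlation of each unit-norm filter with the underlying image patch,
#' divided by the patch norm.  Invariant to global intensity scaling.
#'
#' @param frame numeric matrix (image; finite values).
#' @param bank a [gaborBank()].
#' @return Nested list: \code{[[size]][[orientation]]} response matrices of
#'   the frame's dimensions.
#' @export
s1Filter <- function(frame, bank = gaborBank()) {
  if (!all(is.finite(frame))) stop("'frame' must be finite-valued")
  .s1Apply(frame, bank, .s1Prepare(dim(frame), bank))
}

#' C1 stage: local max pooling of S1 maps
#'
#' For each scale band, responses are pooled by taking the maximum within
#' half-overlapping spatial cells (side = the band's pool size) and across
#' the band's two filter sizes.  Output layout is fixed for a fixed bank
#' and image size: band x orientation x grid cell.
#'
#' @param s1maps output of [s1Filter()] for one frame.
#' @param bank the [gaborBank()] used.
#' @return A numeric \code{C1Feature} vector (all values >= 0) with a
#'   \code{layout} attribute.
#' @export
c1Pool <- function(s1maps, bank = gaborBank()) {
  dims <- dim(s1maps[[1]][[1]])
  feat <- c()
  layout <- character()
  for (b in seq_len(bank$nBands)) {
    p <- bank$poolSizes[b]
    stride <- max(1L, p %/% 2L)
    rStarts <- seq(1L, dims[1], by = stride)
    cStarts <- seq(1L, dims[2], by = stride)
    s1a <- s1maps[[2 * b - 1]]
    s1b <- s1maps[[2 * b]]
    for (oi in seq_along(bank$orientations)) {
      m <- pmax(s1a[[oi]], s1b[[oi]])
      cell <- matrix(0, length(rStarts), length(cStarts))
      for (ri in seq_along(rStarts)) {
        rows <- rStarts[ri]:min(rStarts[ri] + p - 1L, dims[1])
        for (ci in seq_along(cStarts)) {
          cols <- cStarts[ci]:min(cStarts[ci] + p - 1L, dims[2])
          cell[ri, ci] <- max(m[rows, cols])
        }
      }
      feat <- c(feat, as.vector(cell))
      layout <- c(layout, sprintf("band%d_or%g_cell%d", b,
                                  bank$orientations[oi],
                                  seq_along(as.vector(cell))))
    }
  }
  structure(feat, layout = layout, class = "C1Feature")
}

#' C1 feature of a whole stimulus
#'
#' Models every frame independently (processing is treated as
#' instantaneous) and averages the per-frame C1 vectors.
#'
#' @param stack a \code{FrameStack} from [renderFrames()], or a 3D array
#'   (height x width x frames).
#' @param bank a [gaborBank()].
#' @return Mean \code{C1Feature} vector.
#' @export
stimulusFeature <- function(stack, bank = gaborBank()) {
  imgs <- if (inherits(stack, "FrameStack")) stack$images else stack
  if (length(dim(imgs)) != 3 || dim(imgs)[3] < 1) {
    stop("'stack' must contain at least one frame")
  }
  prep <- .s1Prepare(dim(imgs)[1:2], bank)
  acc <- NULL
  nf <- dim(imgs)[3]
  for (f in seq_len(nf)) {
    c1 <- c1Pool(.s1Apply(imgs[, , f], bank, prep), bank)
    acc <- if (is.null(acc)) c1 else acc + c1
  }
  out <- acc / nf
  attributes(out) <- attributes(acc)
  out
}

#' V1 predictor RDM from stimulus C1 features
#'
#' @param features list of 8 \code{C1Feature} vectors (named by stimulus).
#' @return An [RDM-class] of kind \code{"v1"}: entries are
#'   1 - Pearson(feature_i, feature_j), in [0, 2].
#' @export
v1RDM <- function(features) {
  fm <- do.call(cbind, lapply(features, as.numeric))
  if (any(apply(fm, 2, stats::sd) == 0)) {
    stop("zero-variance C1 feature: correlation undefined")
  }
  d <- 1 - stats::cor(fm)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  labels <- names(features)
  if (is.null(labels)) labels <- paste0("s", seq_along(features))
  RDM(d, kind = "v1", labels = labels)
}
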