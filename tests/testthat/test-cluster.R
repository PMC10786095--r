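test_that("voxel thresholding applies the Student-t critical value", {
  dof <- 19
  crit <- qt(1 - 0.001, df = dof)    # 3.5794 at dof = 19
  tvals <- c(-5, 0, crit - 1e-6, crit + 1e-6, 10, NA)
  keep <- voxelThreshold(tvals, dof, 0.001)
  expect_identical(keep, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(sum(voxelThreshold(rep(0, 50), dof, 0.001)), 0L)
  # capped "infinite" flags are always kept
  expect_true(voxelThreshold(100, dof, 1e-6))
  two <- voxelThreshold(c(-10, 10), dof, 0.001, tail = "two")
  expect_identical(two, c(TRUE, TRUE))
  expect_error(voxelThreshold(1, 0, 0.001), "dof")
})

test_that("connectivity changes diagonal adjacency as documented", {
  dim3 <- c(4, 4, 4)
  maskIdx <- seq_len(64)
  b <- rep(FALSE, 64)
  # voxels (1,1,1) and (2,2,1): diagonal in-plane neighbors
  b[1] <- TRUE
  b[1 + 1 + 4] <- TRUE
  cs26 <- labelClusters(b, maskIdx, dim3, 26)
  cs18 <- labelClusters(b, maskIdx, dim3, 18)
  cs6 <- labelClusters(b, maskIdx, dim3, 6)
  expect_identical(nrow(clusterTable(cs26)), 1L)
  expect_identical(nrow(clusterTable(cs18)), 1L)
  expect_identical(nrow(clusterTable(cs6)), 2L)
  empty <- labelClusters(rep(FALSE, 64), maskIdx, dim3, 26)
  expect_identical(nrow(clusterTable(empty)), 0L)
})

test_that("cluster labeling matches a flood-fill oracle on random masks", {
  # independent oracle: repeated dilation-style flood fill on the array
  oracleComponents <- function(arr, connectivity) {
    d <- dim(arr)
    lab <- array(0L, d)
    off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
    off <- off[rowSums(abs(off)) > 0, ]
    keep <- switch(as.character(connectivity),
                   "6" = rowSums(abs(off)) == 1,
                   "18" = rowSums(abs(off)) <= 2,
                   "26" = rep(TRUE, nrow(off)))
    off <- off[keep, ]
    cur <- 0L
    for (idx in which(arr)) {
      if (lab[idx] > 0L) next
      cur <- cur + 1L
      frontier <- idx
      lab[idx] <- cur
      while (length(frontier)) {
        nxt <- integer(0)
        for (f in frontier) {
          ci <- arrayInd(f, d)
          for (r in seq_len(nrow(off))) {
            p <- ci + as.integer(off[r, ])
            if (any(p < 1) || any(p > d)) next
            li <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
            if (arr[li] && lab[li] == 0L) {
              lab[li] <- cur
              nxt <- c(nxt, li)
            }
          }
        }
        frontier <- nxt
      }
    }
    lab
  }
  set.seed(33)
  for (rep in 1:3) {
    conn <- c(6, 18, 26)[rep]
    arr <- array(runif(12^3) < 0.25, c(12, 12, 12))
    cs <- labelClusters(as.vector(arr), seq_len(12^3), c(12, 12, 12), conn)
    lab <- oracleComponents(arr, conn)
    # same partition: component ids may differ, memberships must agree
    ours <- clusterLabels(cs)
    expect_identical(sum(ours > 0), sum(lab > 0))
    for (cl in unique(ours[ours > 0])) {
      vox <- which(ours == cl)
      expect_identical(length(unique(lab[vox])), 1L)
      expect_identical(sum(lab == lab[vox[1]]), length(vox))
    }
    # labels ordered by ascending minimum voxel index
    mins <- tapply(which(ours > 0), ours[ours > 0], min)
    expect_true(all(diff(mins[order(as.integer(names(mins)))]) > 0))
  }
})

test_that("Monte Carlo correction flags planted clusters and orders p by size", {
  set.seed(9)
  dim3 <- c(10, 10, 10)
  mi <- seq_len(1000)
  # one huge planted effect >> noise: survives at the minimal p
  M <- matrix(rnorm(12 * 1000, sd = 0.1), 12, 1000)
  M[, 1:125] <- M[, 1:125] + 3
  spec <- thresholdSpec(n_iter = 200, seed = 4)
  cs <- monteCarloCluster(M, spec, mi, dim3)
  tab <- clusterTable(cs)
  big <- tab[which.max(tab$size), ]
  expect_gte(big$size, 100)
  expect_equal(big$p, 1 / (1 + 200), tolerance = 1e-12)
  expect_true(big$significant)
  # Monte Carlo p monotonically non-increasing in cluster size
  if (nrow(tab) > 1) {
    o <- order(tab$size)
    expect_true(all(diff(tab$p[o]) <= 1e-12))
  }
  # two-sided mode: cluster sizes invariant under global sign flip
  spec2 <- thresholdSpec(n_iter = 100, seed = 4, tail = "two")
  csA <- monteCarloCluster(M, spec2, mi, dim3)
  csB <- monteCarloCluster(-M, spec2, mi, dim3)
  expect_identical(sort(clusterTable(csA)$size), sort(clusterTable(csB)$size))
})

test_that("BH step-up matches hand-evaluated cases and dominates Bonferroni", {
  expect_identical(fdrBH(c(0.01, 0.02, 0.03, 0.5), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdrBH(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(fdrBH(0.04, 0.05), TRUE)
  expect_identical(fdrBH(numeric(0), 0.05), logical(0))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(30)^2
    bh <- fdrBH(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh[bonf]))    # BH rejections contain Bonferroni's
  }
})

test_that("dice follows the exact overlap formula", {
  a <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  b <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  d <- dice(a, b)
  expect_equal(d$dc, 2 * 2 / (4 + 4))
  expect_identical(d$n_common, 2L)
  expect_equal(dice(a, a)$dc, 1)
  expect_equal(dice(a, !a)$dc, 0)
  z <- rep(FALSE, 8)
  dz <- dice(z, z)
  expect_equal(dz$dc, 0)
  expect_true(dz$both_empty)
  expect_error(dice(a, b[1:4]), "different grids")
  # symmetry and monotonicity in the overlap
  expect_equal(dice(a, b)$dc, dice(b, a)$dc)
  b2 <- b; b2[3] <- TRUE; b2[5] <- FALSE   # same |b|, one more common voxel
  expect_gt(dice(a, b2)$dc, dice(a, b)$dc)
})
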