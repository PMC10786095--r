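test_that("searchlight neighborhoods match a brute-force k-nearest oracle", {
  mask <- array(TRUE, c(10, 10, 10))    # solid cube
  k <- 33L
  sl <- defineSearchlights(mask, searchlightSpec(k))
  expect_identical(nrow(sl@neighbors), k)
  expect_identical(ncol(sl@neighbors), 1000L)
  # every neighborhood has exactly k members and contains its center
  for (v in c(1, 57, 500, 1000)) {
    expect_identical(length(unique(sl@neighbors[, v])), k)
    expect_true(v %in% sl@neighbors[, v])
  }
  # brute-force oracle: exhaustive distance sort with index tie-break
  co <- arrayInd(seq_len(1000), c(10, 10, 10))
  for (v in c(1, 123, 555, 1000)) {
    d <- sqrt(colSums((t(co) - co[v, ])^2))
    oracle <- order(d, seq_len(1000))[1:k]
    expect_identical(sort(sl@neighbors[, v]), sort(oracle))
  }
  expect_error(defineSearchlights(array(TRUE, c(2, 2, 2)),
                                  searchlightSpec(20)), "exceeds")
  expect_error(searchlightSpec(1), ">= 2")
})

test_that("regressRDM matches the closed-form normal equations", {
  set.seed(7)
  # independent oracle: explicit standardization + solve of X'X b = X'y
  oracle <- function(y, X) {
    ys <- (y - mean(y)) / sd(y)
    Xs <- apply(X, 2, function(c) (c - mean(c)) / sd(c))
    as.numeric(solve(t(Xs) %*% Xs) %*% t(Xs) %*% ys)
  }
  for (i in 1:100) {
    y <- rnorm(28)
    X <- matrix(rnorm(28 * 4), 28, 4)
    expect_equal(unname(regressRDM(y, X)), oracle(y, X), tolerance = 1e-8)
  }
})

test_that("regressRDM identifies an exactly matching predictor", {
  set.seed(3)
  # orthogonal predictors after centering
  X <- qr.Q(qr(matrix(rnorm(28 * 5), 28, 5)))[, 2:5]
  X <- apply(X, 2, function(c) c - mean(c))
  y <- X[, 2]
  b <- regressRDM(y, X)
  expect_equal(unname(b[2]), 1, tolerance = 1e-8)
  expect_lt(max(abs(b[-2])), 1e-8)
  # coefficients invariant to affine rescaling of y
  b2 <- regressRDM(5 * y + 3, X)
  expect_equal(unname(b), unname(b2), tolerance = 1e-10)
  # errors
  expect_error(regressRDM(rep(1, 28), X), "zero variance")
  expect_error(regressRDM(y, cbind(X[, 1:3], rep(2, 28))), "zero-variance")
  expect_error(regressRDM(y, cbind(X[, c(1, 2, 3, 3)])), "collinear")
})

test_that("pure-noise regressions center on zero", {
  set.seed(12)
  theo <- theoreticalRDMs(tinyLabels())
  X <- sapply(theo, rdmVec)
  coefs <- replicate(1000, regressRDM(rnorm(28), X)[1])
  expect_lt(abs(mean(coefs)), 0.02)
})

test_that("searchlight RSA lifts planted attribute structure", {
  sub <- smallSubject()
  sl <- smallSearchlights()
  theo <- theoreticalRDMs(tinyLabels())
  v1 <- tinyV1()
  m <- searchlightRSA(smallTmaps(), theo, v1, sl)
  expect_s4_class(m, "VoxelMap")
  expect_identical(colnames(mapValues(m)), c("facing", "gender", "emotion", "v1"))
  planted <- plantAmplitudes(sub@effects, sub@labels)
  for (a in c("facing", "gender", "emotion")) {
    roi <- planted$roiIdx[[a]]
    far <- setdiff(seq_len(nrow(mapValues(m))), unlist(planted$roiIdx))
    expect_gt(mean(mapValues(m)[roi, a]) - mean(mapValues(m)[far, a]), 0.05)
  }
  # identical data -> identical maps
  m2 <- searchlightRSA(smallTmaps(), theo, v1, sl)
  expect_identical(mapValues(m), mapValues(m2))
})

test_that("the V1 predictor changes coefficients only where it matters", {
  theo <- theoreticalRDMs(tinyLabels())
  X3 <- sapply(theo, rdmVec)
  v1vec <- rdmVec(tinyV1())
  # y made of facing structure only: v1 is (nearly) uncorrelated with
  # facing, so adding it barely moves the facing coefficient ...
  yF <- rdmVec(theo$facing) + 0
  bF3 <- regressRDM(yF, X3)
  bF4 <- regressRDM(yF, cbind(X3, v1 = v1vec))
  expect_lt(abs(bF4["facing"] - bF3["facing"]), 0.1)
  # ... while y made of v1 structure loads on v1 and is re-attributed
  # when v1 is omitted
  bV4 <- regressRDM(v1vec, cbind(X3, v1 = v1vec))
  bV3 <- regressRDM(v1vec, X3)
  expect_gt(bV4["v1"], 0.8)
  expect_gt(max(abs(bV3 - bV4[1:3])), 0.1)
})

test_that("group RSA Fisher-transforms and tests against zero", {
  expect_equal(bmRSA:::fisherZ(0), 0)
  expect_equal(bmRSA:::fisherZ(0.5), 0.5493, tolerance = 1e-4)
  # three identical subjects: zero variance -> capped t with flags
  m <- VoxelMap(matrix(0.3, 10, 1), mask = 1:10, dim = c(10, 1, 1),
                statNames = "facing")
  g <- groupRSA(list(m, m, m))
  expect_true(all(mapValues(g$facing)[, "t"] == 100))
  expect_true(all(mapValues(g$facing)[, "p"] < 1e-4))
  # mixed-sign means keep their sign
  vals <- matrix(c(rep(0.2, 5), rep(-0.2, 5)), 10, 1)
  maps <- lapply(1:4, function(s) {
    VoxelMap(vals + 0.01 * s, mask = 1:10, dim = c(10, 1, 1),
             statNames = "facing")
  })
  g2 <- groupRSA(maps)
  expect_true(all(mapValues(g2$facing)[1:5, "t"] > 0))
  expect_true(all(mapValues(g2$facing)[6:10, "t"] < 0))
})

test_that("neural RDM vectors skip degenerate searchlights", {
  sl <- defineSearchlights(array(TRUE, c(4, 4, 4)), searchlightSpec(5))
  tm <- matrix(rnorm(64 * 8), 64, 8)
  Y <- neuralRDMVectors(tm, sl)
  expect_identical(dim(Y), c(64L, 28L))
  expect_false(any(attr(Y, "skipped")))
  tmBad <- tm
  tmBad[sl@neighbors[, 1], 2] <- 7   # condition 2 constant in searchlight 1
  Y2 <- neuralRDMVectors(tmBad, sl)
  expect_true(attr(Y2, "skipped")[1])
  expect_true(all(is.na(Y2[1, ])))
})
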