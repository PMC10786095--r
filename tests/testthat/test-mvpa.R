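test_that("pattern demeaning removes amplitude offsets", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE)
  d <- demeanPattern(x)
  expect_equal(rowMeans(d), c(0, 0))
  expect_equal(demeanPattern(d), d)                       # idempotent
  expect_equal(demeanPattern(x + 7), d, tolerance = 1e-12)  # offset invariant
  expect_equal(demeanPattern(rep(3, 5)), rep(0, 5))       # constant -> zeros
})

test_that("noiseless planted patterns decode perfectly; permuted labels at chance", {
  labels <- tinyLabels()
  eff <- smallEffects(noise_sd = 0.2, drift = 0, nuisance_coupling = 0,
                      effect_size = c(facing = 0, gender = 2, emotion = 0))
  sub <- simulateSubject(designSpec(), eff, labels, seed = 17)
  rb <- runBetas(sub)
  sl <- defineSearchlights(subjectMask(sub), searchlightSpec(19))
  planted <- plantAmplitudes(eff, labels)
  roi <- planted$roiIdx$gender[1:15]
  am <- searchlightClassify(rb$betas, rb$condition, rb$run, labels, "gender",
                            sl, centers = roi)
  acc <- mapValues(am)[roi, 1]
  expect_true(all(acc > 0.95))   # near-noiseless, separable
  # searchlights away from every ROI are uninformative
  far <- setdiff(seq_len(sum(subjectMask(sub))), unlist(planted$roiIdx))[1:15]
  amFar <- searchlightClassify(rb$betas, rb$condition, rb$run, labels,
                               "gender", sl, centers = far)
  accFar <- mean(mapValues(amFar)[far, 1])
  expect_lt(abs(accFar - 0.5), 1.96 * sqrt(0.25 / 48))
  # permuted sample labels: grand mean accuracy within the band of 0.5
  set.seed(3)
  condPerm <- sample(rb$condition)
  amPerm <- searchlightClassify(rb$betas, condPerm, rb$run, labels,
                                "gender", sl, centers = roi)
  expect_lt(abs(mean(mapValues(amPerm)[roi, 1]) - 0.5),
            1.96 * sqrt(0.25 / 48))
})

test_that("demeaning protects decoding from additive amplitude confounds", {
  labels <- tinyLabels()
  eff <- smallEffects(noise_sd = 0.3, drift = 0, nuisance_coupling = 0,
                      effect_size = c(facing = 0, gender = 1.5, emotion = 0))
  sub <- simulateSubject(designSpec(), eff, labels, seed = 23)
  rb <- runBetas(sub)
  sl <- defineSearchlights(subjectMask(sub), searchlightSpec(19))
  roi <- plantAmplitudes(eff, labels)$roiIdx$gender[1:10]
  # add a class-correlated uniform amplitude confound to every pattern
  confound <- rb$betas
  cls <- attributeSigns(labels)[match(rb$condition, labels$id), "gender"]
  confound <- confound + matrix(5 * cls, nrow(confound), 48, byrow = TRUE)
  a1 <- searchlightClassify(rb$betas, rb$condition, rb$run, labels, "gender",
                            sl, centers = roi, demean = TRUE)
  a2 <- searchlightClassify(confound, rb$condition, rb$run, labels, "gender",
                            sl, centers = roi, demean = TRUE)
  expect_equal(mapValues(a1)[roi, 1], mapValues(a2)[roi, 1],
               tolerance = 1e-8)
})

test_that("degenerate training patterns score at chance with a warning", {
  labels <- tinyLabels()
  betas <- matrix(0, 30, 48)     # all-identical patterns
  sl <- defineSearchlights(array(TRUE, c(5, 3, 2)), searchlightSpec(5))
  expect_warning(
    am <- searchlightClassify(betas, rep(labels$id, 6),
                              rep(1:6, each = 8), labels, "facing", sl,
                              centers = 1),
    "degenerate")
  expect_equal(unname(mapValues(am)[1, 1]), 0.5)
})

test_that("cluster accuracies average the map over cluster voxels", {
  dimg <- c(6, 6, 6)
  mi <- seq_len(216)
  b <- rep(FALSE, 216); b[c(1:5, 100:104)] <- TRUE
  cs <- labelClusters(b, mi, dimg, 26)
  uni <- VoxelMap(matrix(0.7, 216, 1), mask = mi, dim = dimg,
                  statNames = "accuracy")
  acc <- clusterAccuracy(uni, cs)
  expect_true(all(abs(acc - 0.7) < 1e-12))
  # oracle: brute-force mean over enumerated voxels
  vals <- runif(216)
  vm <- VoxelMap(matrix(vals, ncol = 1), mask = mi, dim = dimg,
                 statNames = "accuracy")
  acc2 <- clusterAccuracy(vm, cs)
  for (cl in clusterTable(cs)$cluster) {
    expect_equal(unname(acc2[paste0("cluster", cl)]),
                 mean(vals[clusterLabels(cs) == cl]), tolerance = 1e-12)
  }
  # single-voxel cluster
  b1 <- rep(FALSE, 216); b1[7] <- TRUE
  cs1 <- labelClusters(b1, mi, dimg, 26)
  expect_equal(unname(clusterAccuracy(vm, cs1)), vals[7])
})

test_that("accuracy tests assign the three display levels", {
  set.seed(6)
  mk <- function(own, oth1, oth2, cluster, network) {
    do.call(rbind, lapply(1:20, function(s) {
      data.frame(subject = s, cluster = cluster,
                 attribute = c(network, setdiff(c("facing", "gender",
                                                 "emotion"), network)),
                 accuracy = c(own + rnorm(1, 0, 0.02),
                              oth1 + rnorm(1, 0, 0.02),
                              oth2 + rnorm(1, 0, 0.02)))
    }))
  }
  acc <- rbind(mk(0.9, 0.5, 0.5, "c1", "gender"),   # higher than both
               mk(0.8, 0.8, 0.5, "c2", "gender"),   # higher than one
               mk(0.7, 0.7, 0.7, "c3", "gender"),   # only above chance
               mk(0.5, 0.5, 0.5, "c4", "gender"))   # nothing
  tests <- accuracyTests(acc, c(c1 = "gender", c2 = "gender",
                                c3 = "gender", c4 = "gender"))
  expect_identical(tests$level, c(3L, 2L, 1L, 0L))
  # identical accuracy vectors give paired t of 0
  same <- mk(0.7, 0.7, 0.7, "c9", "facing")
  same$accuracy <- rep(0.7, nrow(same))
  t9 <- accuracyTests(same, c(c9 = "facing"))
  expect_identical(t9$t_vs_gender, 0)
  expect_identical(t9$p_vs_gender, 1)
  # all subjects exactly at chance: nothing is significant
  chance <- mk(0.5, 0.5, 0.5, "c0", "emotion")
  chance$accuracy <- rep(0.5, nrow(chance))
  t0 <- accuracyTests(chance, c(c0 = "emotion"))
  expect_identical(t0$level, 0L)
})
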