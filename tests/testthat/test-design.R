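test_that("design spec validates the block arithmetic", {
  expect_error(designSpec(blocks_per_run = 20), "8 \\* reps")
  expect_error(designSpec(block_duration = 11, blocks_per_run = 24),
               "multiples of tr")
  s <- designSpec()
  expect_identical(s$tr, 2)
  expect_identical(s$n_runs, 6)
})

test_that("the default timeline reproduces the run arithmetic", {
  ids <- tinyLabels()$id
  tl <- buildTimeline(designSpec(), ids, seed = 3)
  expect_equal(attr(tl, "total_duration"), 438)
  expect_identical(attr(tl, "n_volumes"), 219L)
  # 24 stimulus blocks, each stimulus exactly 3 times
  stim <- tl$trial_type[tl$trial_type != "fixation"]
  expect_identical(length(stim), 24L)
  expect_true(all(table(stim) == 3))
  # events tile [0, 438] with no gaps or overlaps
  expect_equal(tl$onset, cumsum(c(0, tl$duration[-nrow(tl)])), tolerance = 1e-9)
  expect_equal(sum(tl$duration), attr(tl, "total_duration"))
  # determinism
  tl2 <- buildTimeline(designSpec(), ids, seed = 3)
  expect_identical(tl$trial_type, tl2$trial_type)
  tl3 <- buildTimeline(designSpec(), ids, seed = 4)
  expect_false(identical(tl$trial_type, tl3$trial_type))
})

test_that("rating simulation emits the 96-trial table", {
  rt <- simulateRatings(tinyLabels(), slope = 1.5, criterion_sd = 1, seed = 2)
  expect_identical(nrow(rt), 96L)
  expect_true(all(rt$rating %in% 1:7))
  expect_identical(nrow(unique(rt[c("stimulus_id", "attribute", "repetition")])),
                   96L)
  # degenerate cases
  flat <- simulateRatings(tinyLabels(), slope = 0, criterion_sd = 0, seed = 1)
  expect_true(all(flat$rating == 4))
  sat <- simulateRatings(tinyLabels(), slope = 10, criterion_sd = 0, seed = 1)
  expect_true(all(sat$rating %in% c(1, 7)))
  signs <- attributeSigns(tinyLabels())
  s <- signs[cbind(match(sat$stimulus_id, tinyLabels()$id),
                   match(sat$attribute, colnames(signs)))]
  expect_true(all(sat$rating[s > 0] == 7) && all(sat$rating[s < 0] == 1))
})

test_that("rating exclusion utility flags unsure and outlying subjects", {
  set.seed(8)
  tables <- lapply(1:10, function(s) simulateRatings(seed = s))
  unsure <- simulateRatings(slope = 0, criterion_sd = 0.1, seed = 99)
  flags <- ratingExclusionFlags(c(tables, list(unsure)))
  expect_true(flags[11])
  expect_false(any(flags[1:10]))
})

test_that("planted amplitudes follow the additive effect formula", {
  labels <- tinyLabels()
  # all zero effects -> constant baseline
  eff0 <- smallEffects(effect_size = c(facing = 0, gender = 0, emotion = 0),
                       idiosyncratic_sd = 0)
  p0 <- plantAmplitudes(eff0, labels)
  expect_true(all(p0$truth == eff0$evoked_baseline))
  # facing-only effect without tuning heterogeneity: within-facing
  # difference 0, between-facing difference exactly 2 x effect in the ROI
  eff1 <- smallEffects(effect_size = c(facing = 0.8, gender = 0, emotion = 0),
                       tuning_sd = 0, idiosyncratic_sd = 0)
  p1 <- plantAmplitudes(eff1, labels)
  roi <- p1$roiIdx$facing
  left <- which(labels$facing == "left")
  right <- which(labels$facing == "right")
  expect_lt(max(abs(p1$truth[roi, left[1]] - p1$truth[roi, left[2]])), 1e-12)
  expect_equal(unname(unique(p1$truth[roi, right[1]] - p1$truth[roi, left[1]])),
               2 * 0.8, tolerance = 1e-12)
  out <- setdiff(seq_len(nrow(p1$truth)), unlist(p1$roiIdx))
  expect_true(all(p1$truth[out, ] == eff1$evoked_baseline))
  # multiplicative interaction: gender contrast magnitude differs between
  # happy and sad stimuli in the coupled ROI
  s <- attributeSigns(labels)
  mh <- which(s[, "gender"] > 0 & s[, "emotion"] > 0)[1]
  fh <- which(s[, "gender"] < 0 & s[, "emotion"] > 0)[1]
  ms <- which(s[, "gender"] > 0 & s[, "emotion"] < 0)[1]
  fs <- which(s[, "gender"] < 0 & s[, "emotion"] < 0)[1]
  effM <- smallEffects(effect_size = c(facing = 0, gender = 1, emotion = 0),
                       interaction = c("gender*emotion" = 0.5),
                       tuning_sd = 0, idiosyncratic_sd = 0)
  pM <- plantAmplitudes(effM, labels)
  roiG <- pM$roiIdx$gender
  gcHappy <- unname(pM$truth[roiG[1], mh] - pM$truth[roiG[1], fh])
  gcSad <- unname(pM$truth[roiG[1], ms] - pM$truth[roiG[1], fs])
  expect_equal(gcHappy, 2 + 2 * 0.5, tolerance = 1e-12)
  expect_equal(gcSad, 2 - 2 * 0.5, tolerance = 1e-12)
  # additive cross-encoding: ROI_gender also carries emotion-signed structure
  effI <- smallEffects(effect_size = c(facing = 0, gender = 1, emotion = 0),
                       interaction = c("gender:emotion" = 0.5),
                       tuning_sd = 0, idiosyncratic_sd = 0)
  pI <- plantAmplitudes(effI, labels)
  roiG <- pI$roiIdx$gender
  expect_equal(unname(pI$truth[roiG[1], mh] - pI$truth[roiG[1], ms]), 2 * 0.5,
               tolerance = 1e-12)
  # overlapping ROIs require an explicit combination rule
  rois <- defaultROIs(c(12, 12, 12))
  rois$gender <- rois$facing
  effO <- smallEffects(rois = rois)
  expect_error(plantAmplitudes(effO, labels), "overlap")
  expect_silent(plantAmplitudes(effO, labels, combine = "additive"))
})

test_that("simulated runs are linear in the planted amplitudes", {
  labels <- tinyLabels()
  ids <- labels$id
  tl <- buildTimeline(designSpec(), ids, seed = 5)
  eff <- smallEffects(noise_sd = 0, drift = 0, nuisance_coupling = 0)
  p <- plantAmplitudes(eff, labels)
  nu <- matrix(0, 219, 6)
  one <- p$truth
  one[] <- 0
  one[5, 3] <- 1
  run <- simulateRun(tl, one, eff, nu, seed = 1)
  # noiseless single-amplitude signal equals the HRF-convolved regressor
  ev <- tl[tl$trial_type == ids[3], ]
  reg <- bmRSA:::hrfRegressor(ev$onset, ev$duration, 2, 219)
  expect_equal(run[, 5] - 100, reg, tolerance = 1e-9)
  expect_true(all(abs(run[, -5] - 100) < 1e-12))
  # doubling an amplitude doubles that contribution
  two <- one; two[5, 3] <- 2
  run2 <- simulateRun(tl, two, eff, nu, seed = 1)
  expect_equal(run2[, 5] - 100, 2 * (run[, 5] - 100), tolerance = 1e-9)
  # additivity of two planted effects
  oneB <- one; oneB[] <- 0; oneB[5, 7] <- 1.5
  both <- one + oneB
  expect_equal(simulateRun(tl, both, eff, nu, 1)[, 5] - 100,
               (run[, 5] - 100) +
                 (simulateRun(tl, oneB, eff, nu, 1)[, 5] - 100),
               tolerance = 1e-9)
})

test_that("noise has the requested lag-1 autocorrelation", {
  labels <- tinyLabels()
  tl <- buildTimeline(designSpec(), labels$id, seed = 1)
  eff <- smallEffects(noise_sd = 1, ar1 = 0.3, drift = 0,
                      nuisance_coupling = 0,
                      effect_size = c(facing = 0, gender = 0, emotion = 0),
                      idiosyncratic_sd = 0, evoked_baseline = 0)
  p <- plantAmplitudes(eff, labels)
  run <- simulateRun(tl, p$truth, eff, matrix(0, 219, 6), seed = 42)
  ac <- apply(run[, 1:600], 2, function(x) cor(x[-1], x[-219]))
  expect_lt(abs(mean(ac) - 0.3), 0.05)
})

test_that("subjects are bit-reproducible from their seed", {
  s1 <- simulateSubject(designSpec(), smallEffects(), tinyLabels(), seed = 7)
  s2 <- simulateSubject(designSpec(), smallEffects(), tinyLabels(), seed = 7)
  expect_identical(subjectRuns(s1), subjectRuns(s2))
  expect_identical(subjectTruth(s1), subjectTruth(s2))
  s3 <- simulateSubject(designSpec(), smallEffects(), tinyLabels(), seed = 8)
  expect_false(identical(subjectRuns(s1)[[1]], subjectRuns(s3)[[1]]))
})

test_that("groups share geometry but not noise", {
  g <- simulateGroup(2, designSpec(), smallEffects(), tinyLabels(),
                     base_seed = 1)
  expect_identical(subjectMask(g[[1]]), subjectMask(g[[2]]))
  expect_false(identical(subjectRuns(g[[1]])[[1]], subjectRuns(g[[2]])[[1]]))
  expect_error(simulateGroup(1, designSpec(), smallEffects()), ">= 2")
})
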