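# Shared fixtures, memoised so expensive objects are built once per run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

tinyLabels <- function() memo("labels", stimulusLabels())

# Small stimulus set for walker/V1 unit tests (3 frames, 48 px).
tinyStimuli <- function() {
  memo("tinyStimuli",
       buildStimulusSet(n_frames = 3, image_size = 48, render = TRUE))
}

tinyBank <- function() memo("tinyBank", gaborBank())

# One small simulated subject (12^3 grid) reused across GLM/RSA tests.
smallEffects <- function(...) {
  effectSpec(grid_shape = c(12, 12, 12), ...)
}

smallSubject <- function() {
  memo("smallSubject",
       simulateSubject(designSpec(), smallEffects(), tinyLabels(), seed = 101))
}

smallTmaps <- function() memo("smallTmaps", conditionTMaps(smallSubject()))

smallSearchlights <- function() {
  memo("smallSL",
       defineSearchlights(subjectMask(smallSubject()), searchlightSpec(19)))
}

# Cheap V1 RDM for unit tests (not the full-resolution study version).
tinyV1 <- function() {
  memo("tinyV1", v1RDM(lapply(tinyStimuli()$stacks, stimulusFeature,
                              bank = tinyBank())))
}
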