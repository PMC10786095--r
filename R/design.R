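# Block-design timeline and hemodynamic response model.

#' Block-design acquisition specification
#'
#' Defaults reproduce the study design: TR 2 s, 6 runs of 24 stimulus
#' blocks of 12 s (each of the 8 stimuli three times per run, random
#' order), 6-s fixations between blocks plus one leading fixation, giving
#' 438 s and 219 volumes per run.
#'
#' @param tr repetition time in seconds.
#' @param n_runs number of runs.
#' @param blocks_per_run stimulus blocks per run; must equal
#'   \code{8 * reps_per_stimulus_per_run}.
#' @param block_duration stimulus block duration (s).
#' @param fixation_duration fixation block duration (s).
#' @param reps_per_stimulus_per_run repetitions of each stimulus per run.
#' @param leading_fixation prepend a fixation block before the first
#'   stimulus block.
#' @return A \code{DesignSpec} list.
#' @export
designSpec <- function(tr = 2, n_runs = 6, blocks_per_run = 24,
                       block_duration = 12, fixation_duration = 6,
                       reps_per_stimulus_per_run = 3,
                       leading_fixation = TRUE) {
  if (blocks_per_run != 8 * reps_per_stimulus_per_run) {
    stop("'blocks_per_run' must equal 8 * reps_per_stimulus_per_run")
  }
  for (d in c(block_duration, fixation_duration)) {
    if (abs(d / tr - round(d / tr)) > 1e-9) {
      stop("block and fixation durations must be integer multiples of tr")
    }
  }
  structure(list(tr = tr, n_runs = n_runs, blocks_per_run = blocks_per_run,
                 block_duration = block_duration,
                 fixation_duration = fixation_duration,
                 reps_per_stimulus_per_run = reps_per_stimulus_per_run,
                 leading_fixation = leading_fixation),
            class = "DesignSpec")
}

#' Build one run's event timeline
#'
#' Stimulus blocks in seeded random order (each stimulus exactly
#' \code{reps_per_stimulus_per_run} times), a fixation after every block
#' and one leading fixation, tiling \code{[0, total_duration]} with no gaps.
#'
#' @param spec a [designSpec()].
#' @param stimulus_ids character(8) stimulus identifiers.
#' @param seed integer seed for the block order.
#' @return A \code{Timeline} data frame (\code{onset}, \code{duration},
#'   \code{trial_type}) with attributes \code{total_duration} and
#'   \code{n_volumes}.
#' @examples
#' tl <- buildTimeline(designSpec(), paste0("s", 1:8), seed = 1)
#' attr(tl, "n_volumes")  # 219
#' @export
buildTimeline <- function(spec, stimulus_ids, seed = 1) {
  stopifnot(inherits(spec, "DesignSpec"), length(stimulus_ids) == 8)
  set.seed(seed)
  blocks <- sample(rep(stimulus_ids, spec$reps_per_stimulus_per_run))
  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       trial_type = character(0))
  t0 <- 0
  addEvent <- function(type, dur) {
    events[nrow(events) + 1, ] <<- list(t0, dur, type)
    t0 <<- t0 + dur
  }
  if (spec$leading_fixation) addEvent("fixation", spec$fixation_duration)
  for (b in blocks) {
    addEvent(b, spec$block_duration)
    addEvent("fixation", spec$fixation_duration)
  }
  total <- t0
  nvol <- total / spec$tr
  if (abs(nvol - round(nvol)) > 1e-9) stop("run length not a multiple of tr")
  structure(events, total_duration = total, n_volumes = as.integer(round(nvol)),
            tr = spec$tr, class = c("Timeline", "data.frame"))
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style constants: response peak around 6 s, undershoot around 16 s,
#' undershoot ratio 1/6.
#'
#' @param t time in seconds (vector).
#' @return HRF values (unnormalized).
#' @export
canonicalHRF <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

# HRF-convolved regressor for given onsets/durations, sampled at volume
# times (0, tr, 2 tr, ...).  Scaled so that an isolated block of
# 'refDuration' seconds peaks at 1, making planted amplitudes interpretable
# as peak percent-signal change.
hrfRegressor <- function(onsets, durations, tr, n_volumes,
                         refDuration = durations[1], dt = 0.1) {
  total <- n_volumes * tr
  grid <- seq(0, total + 32, by = dt)
  box <- numeric(length(grid))
  for (i in seq_along(onsets)) {
    box[grid >= onsets[i] & grid < onsets[i] + durations[i]] <- 1
  }
  h <- canonicalHRF(grid - min(grid))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  # reference single-block peak for normalization
  refbox <- numeric(length(grid))
  refbox[grid < refDuration] <- 1
  refconv <- stats::convolve(refbox, rev(h), type = "open")[seq_along(grid)] * dt
  scale <- max(refconv)
  volTimes <- (seq_len(n_volumes) - 1) * tr
  stats::approx(grid, conv, xout = volTimes, rule = 2)$y / scale
}

#' Write a timeline as a BIDS-style events table
#'
#' @param timeline a \code{Timeline}.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeEventsTSV <- function(timeline, path) {
  utils::write.table(as.data.frame(timeline), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
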