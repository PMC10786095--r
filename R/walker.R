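# Parametric point-light walker generator.
#
# The stimuli are synthetic stand-ins for motion-capture walkers: a 15-joint
# skeleton animated by sinusoids at the gait frequency, morphed along two
# hand-designed linear axes (gender: shoulder/hip proportions and lateral
# sway; emotion: vertical bounce, arm swing and head/torso inclination), and
# orthographically projected at one of two side-view azimuths (45 deg /
# 135 deg, symmetric about the frontal plane).  Morph levels are expressed
# in "SD units" so that the stimulus set uses +/- 6 as in a morphable-walker
# space.  The left-facing walker is the laterally mirrored body rotated to
# the opposite azimuth, so projected x-coordinates of the two facings are
# exact mirror images frame by frame.

.JOINTS <- c("head", "neck", "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
             "l_wrist", "r_wrist", "pelvis", "l_hip", "r_hip",
             "l_knee", "r_knee", "l_ankle", "r_ankle")

#' Point-light walker parameters
#'
#' @param facing \code{"left"} or \code{"right"}; rendered as the two
#'   side views at 45 and 135 degrees azimuth.
#' @param gender_level signed morph level in SD units on the gender axis
#'   (positive = more male-typical proportions; the stimulus set uses +/-6).
#' @param emotion_level signed morph level in SD units on the happy--sad
#'   axis (positive = happy).
#' @param cycle_duration gait cycle duration in seconds (default 1).
#' @param n_dots number of dots; must be 15.
#' @return A \code{WalkerParams} list.
#' @export
walkerParams <- function(facing = c("right", "left"), gender_level = 0,
                         emotion_level = 0, cycle_duration = 1,
                         n_dots = 15L) {
  facing <- match.arg(facing)
  stopifnot(is.finite(gender_level), is.finite(emotion_level))
  if (cycle_duration <= 0) stop("'cycle_duration' must be positive")
  if (n_dots != 15L) stop("walkers are defined on exactly 15 dots")
  structure(list(facing = facing, gender_level = gender_level,
                 emotion_level = emotion_level,
                 cycle_duration = cycle_duration, n_dots = 15L),
            class = "WalkerParams")
}

# Mean 3D pose: columns x (lateral), y (vertical), z (anterior-posterior),
# in normalized units (walker height ~ 1).
.walkerBasePose <- function() {
  m <- rbind(
    head       = c(0.00, 0.95, 0),
    neck       = c(0.00, 0.82, 0),
    l_shoulder = c(-0.11, 0.80, 0),
    r_shoulder = c(0.11, 0.80, 0),
    l_elbow    = c(-0.13, 0.62, 0),
    r_elbow    = c(0.13, 0.62, 0),
    l_wrist    = c(-0.14, 0.46, 0),
    r_wrist    = c(0.14, 0.46, 0),
    pelvis     = c(0.00, 0.50, 0),
    l_hip      = c(-0.08, 0.48, 0),
    r_hip      = c(0.08, 0.48, 0),
    l_knee     = c(-0.08, 0.26, 0),
    r_knee     = c(0.08, 0.26, 0),
    l_ankle    = c(-0.08, 0.04, 0),
    r_ankle    = c(0.08, 0.04, 0)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

# 3D body-frame position of all 15 joints at times t (vector), before
# facing rotation.  Linear in (gender_level, emotion_level) by construction:
# pose(t) = base(t) + g * genderAxis(t) + e * emotionAxis(t).
.walkerBody <- function(t, gender_level, emotion_level, cycle_duration) {
  nt <- length(t)
  f <- 1 / cycle_duration
  ph <- 2 * pi * f * t                     # gait phase
  base <- .walkerBasePose()
  # per-joint anterior-posterior swing amplitude and phase (left leg at 0)
  zamp <- c(head = 0, neck = 0,
            l_shoulder = 0.02, r_shoulder = 0.02,
            l_elbow = 0.07, r_elbow = 0.07,
            l_wrist = 0.12, r_wrist = 0.12,
            pelvis = 0, l_hip = 0.03, r_hip = 0.03,
            l_knee = 0.10, r_knee = 0.10,
            l_ankle = 0.16, r_ankle = 0.16)
  # arms counter-swing against ipsilateral legs
  zphase <- c(head = 0, neck = 0,
              l_shoulder = pi, r_shoulder = 0,
              l_elbow = pi, r_elbow = 0,
              l_wrist = pi, r_wrist = 0,
              pelvis = 0, l_hip = 0, r_hip = pi,
              l_knee = 0, r_knee = pi,
              l_ankle = 0, r_ankle = pi)
  out <- array(0, c(nt, 15, 3), dimnames = list(NULL, .JOINTS, c("x", "y", "z")))
  sway <- 0.010 * sin(ph)          # lateral sway at gait frequency
  bounce <- 0.015 * sin(2 * ph)    # vertical bounce at twice gait frequency
  for (j in seq_len(15)) {
    out[, j, 1] <- base[j, 1] + sway
    out[, j, 2] <- base[j, 2] + bounce
    out[, j, 3] <- base[j, 3] + zamp[j] * sin(ph + zphase[j])
  }
  if (gender_level != 0) {
    g <- .genderAxis(t, cycle_duration)
    out <- out + gender_level * g
  }
  if (emotion_level != 0) {
    e <- .emotionAxis(t, cycle_duration)
    out <- out + emotion_level * e
  }
  out
}

# Gender axis per SD unit: broader shoulders / narrower hips with level,
# plus increased lateral sway of the upper body.
.genderAxis <- function(t, cycle_duration) {
  nt <- length(t)
  ph <- 2 * pi * t / cycle_duration
  ax <- array(0, c(nt, 15, 3))
  dx <- c(head = 0, neck = 0,
          l_shoulder = -0.002, r_shoulder = 0.002,
          l_elbow = -0.0023, r_elbow = 0.0023,
          l_wrist = -0.0026, r_wrist = 0.0026,
          pelvis = 0, l_hip = 0.0013, r_hip = -0.0013,
          l_knee = 0.0013, r_knee = -0.0013,
          l_ankle = 0.0013, r_ankle = -0.0013)
  upper <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  swayAmp <- 0.004
  for (j in seq_len(15)) {
    ax[, j, 1] <- dx[j] + upper[j] * swayAmp * sin(ph)
  }
  ax
}

# Emotion axis per SD unit (positive = happy): raised, upright head and
# neck, larger vertical bounce, larger arm swing; negative levels slump
# the head/torso forward and damp the movement.
.emotionAxis <- function(t, cycle_duration) {
  nt <- length(t)
  ph <- 2 * pi * t / cycle_duration
  ax <- array(0, c(nt, 15, 3))
  dy <- c(head = 0.0018, neck = 0.0009, l_shoulder = 0.0004, r_shoulder = 0.0004,
          rep(0, 11))
  dz <- c(head = -0.0013, neck = -0.0007, rep(0, 13))
  bounceAmp <- 0.002
  armAmp <- c(l_elbow = 0.002, r_elbow = 0.002, l_wrist = 0.004, r_wrist = 0.004)
  armPh <- c(l_elbow = pi, r_elbow = 0, l_wrist = pi, r_wrist = 0)
  for (j in seq_len(15)) {
    jn <- .JOINTS[j]
    ax[, j, 2] <- dy[j] + bounceAmp * sin(2 * ph)
    ax[, j, 3] <- dz[j]
    if (jn %in% names(armAmp)) {
      ax[, j, 3] <- ax[, j, 3] + armAmp[jn] * sin(ph + armPh[jn])
    }
  }
  ax
}

#' Generate a point-light walker trajectory
#'
#' Evaluates the morphable walker at \code{n_frames} time points covering
#' one or more gait cycles and orthographically projects it at the facing
#' azimuth.  Deterministic for identical parameters; the morph axes are
#' applied additively in the body frame before projection.
#'
#' @param params a [walkerParams()] object.
#' @param n_frames number of frames (>= 2).
#' @param frame_rate sampling rate in Hz (default 30).
#' @return A \code{DotTrajectory}: list with \code{positions}
#'   (\code{n_frames} x 15 x 2 image-plane coordinates), \code{times},
#'   \code{frame_rate} and \code{params}.
#' @examples
#' traj <- makeWalker(walkerParams("right", 6, -6), n_frames = 30)
#' dim(traj$positions)
#' @export
makeWalker <- function(params, n_frames, frame_rate = 30) {
  if (!inherits(params, "WalkerParams")) stop("'params' must be walkerParams()")
  if (!is.numeric(n_frames) || n_frames < 2) {
    stop("'n_frames' must be a count >= 2")
  }
  n_frames <- as.integer(n_frames)
  t <- (seq_len(n_frames) - 1) / frame_rate
  body <- .walkerBody(t, params$gender_level, params$emotion_level,
                      params$cycle_duration)
  beta <- 45 * pi / 180
  if (params$facing == "left") {
    body[, , 1] <- -body[, , 1]   # lateral mirror
    beta <- -beta                 # opposite azimuth
  }
  xr <- body[, , 1] * cos(beta) + body[, , 3] * sin(beta)
  pos <- array(0, c(n_frames, 15, 2),
               dimnames = list(NULL, .JOINTS, c("x", "y")))
  pos[, , 1] <- xr
  pos[, , 2] <- body[, , 2]
  structure(list(positions = pos, times = t, frame_rate = frame_rate,
                 params = params), class = "DotTrajectory")
}

#' Render a dot trajectory into an image stack
#'
#' Dots are drawn as isotropic Gaussian blobs (peak intensity 1, sigma =
#' \code{dot_radius / 2}) on a dark background; overlapping blobs are
#' clipped at 1.  The canvas aspect ratio matches the 6.9 x 3.9 degree
#' stimulus window (height x width).
#'
#' @param traj a \code{DotTrajectory} from [makeWalker()].
#' @param image_size image height in pixels; width is derived from the
#'   6.9:3.9 aspect ratio.
#' @param dot_radius dot radius in pixels.
#' @return A \code{FrameStack}: list with \code{images} (height x width x
#'   frames, intensities in [0, 1]), \code{dot_radius} and \code{params}.
#' @export
renderFrames <- function(traj, image_size = 128, dot_radius = 2) {
  stopifnot(inherits(traj, "DotTrajectory"))
  H <- as.integer(image_size)
  W <- as.integer(round(image_size * 3.9 / 6.9))
  nf <- dim(traj$positions)[1]
  # world window: y in [-0.075, 1.075], x centered with matched aspect
  wh <- 1.15
  ww <- wh * 3.9 / 6.9
  sigma <- dot_radius / 2
  ext <- ceiling(3 * sigma)
  imgs <- array(0, c(H, W, nf))
  for (f in seq_len(nf)) {
    for (d in seq_len(15)) {
      x <- traj$positions[f, d, 1]
      y <- traj$positions[f, d, 2]
      # pixel coordinates: row 1 = top of the window
      px <- (x + ww / 2) / ww * (W - 1) + 1
      py <- (1.075 - y) / wh * (H - 1) + 1
      if (px < 1 || px > W || py < 1 || py > H) {
        stop(sprintf("dot %d of frame %d falls outside the canvas", d, f))
      }
      rows <- max(1, floor(py - ext)):min(H, ceiling(py + ext))
      cols <- max(1, floor(px - ext)):min(W, ceiling(px + ext))
      blob <- exp(-(outer((rows - py)^2, (cols - px)^2, "+")) / (2 * sigma^2))
      imgs[rows, cols, f] <- pmin(1, imgs[rows, cols, f] + blob)
    }
  }
  structure(list(images = imgs, dot_radius = dot_radius, params = traj$params),
            class = "FrameStack")
}

#' Build the eight-stimulus set (2 facings x 2 genders x 2 emotions)
#'
#' Generates the full attribute crossing used throughout the pipeline:
#' facing left/right, gender at +/- \code{gender_sd} SD units (male
#' positive) and emotional state at +/- \code{emotion_sd} (happy positive).
#'
#' @param gender_sd,emotion_sd morph magnitudes in SD units (default 6).
#' @param n_frames frames per stimulus (default 30 = one 1-s cycle at 30 Hz).
#' @param frame_rate sampling rate in Hz.
#' @param image_size,dot_radius rendering parameters; set
#'   \code{render = FALSE} to return trajectories only.
#' @param render render frame stacks (default TRUE).
#' @return List with \code{labels} (data frame: id, facing, gender, emotion),
#'   \code{trajectories} and (if rendered) \code{stacks}, all in label order.
#' @examples
#' ss <- buildStimulusSet(n_frames = 4, image_size = 48, render = TRUE)
#' ss$labels
#' @export
buildStimulusSet <- function(gender_sd = 6, emotion_sd = 6, n_frames = 30,
                             frame_rate = 30, image_size = 128,
                             dot_radius = 2, render = TRUE) {
  if (gender_sd < 0 || emotion_sd < 0) stop("morph SDs must be >= 0")
  labels <- expand.grid(emotion = c("happy", "sad"),
                        gender = c("female", "male"),
                        facing = c("left", "right"),
                        stringsAsFactors = FALSE)[, 3:1]
  labels$id <- sprintf("%s_%s_%s",
                       toupper(substr(labels$facing, 1, 1)),
                       toupper(substr(labels$gender, 1, 1)),
                       toupper(substr(labels$emotion, 1, 1)))
  labels <- labels[, c("id", "facing", "gender", "emotion")]
  rownames(labels) <- labels$id
  trajs <- vector("list", 8)
  stacks <- if (render) vector("list", 8) else NULL
  for (i in seq_len(8)) {
    g <- if (labels$gender[i] == "male") gender_sd else -gender_sd
    e <- if (labels$emotion[i] == "happy") emotion_sd else -emotion_sd
    p <- walkerParams(labels$facing[i], g, e)
    trajs[[i]] <- makeWalker(p, n_frames, frame_rate)
    if (render) {
      stacks[[i]] <- renderFrames(trajs[[i]], image_size, dot_radius)
    }
  }
  names(trajs) <- labels$id
  if (render) names(stacks) <- labels$id
  out <- list(labels = labels, trajectories = trajs)
  if (render) out$stacks <- stacks
  out
}

#' Export a trajectory as a per-frame dot table
#'
#' Writes a TSV with columns \code{frame}, \code{dot_id}, \code{x}, \code{y}.
#'
#' @param traj a \code{DotTrajectory}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeTrajectoryTSV <- function(traj, path) {
  stopifnot(inherits(traj, "DotTrajectory"))
  nf <- dim(traj$positions)[1]
  df <- data.frame(
    frame = rep(seq_len(nf), each = 15),
    dot_id = rep(.JOINTS, nf),
    x = as.vector(t(traj$positions[, , 1])),
    y = as.vector(t(traj$positions[, , 2]))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
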