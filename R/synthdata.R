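# Synthetic 17-joint motion: analytic class archetypes (posture template +
# per-class kinematics) with Gaussian pixel noise. Built for controllability,
# not biomechanical realism: every archetype is a deterministic function of
# time so separability can be dialed with a single noise parameter.

# Upright COCO-17 posture template, pixel offsets from the hip midpoint
# (x right, y down). Roughly a 170-pixel-tall figure.
skeleton_template <- function() {
  m <- rbind(
    nose = c(0, -75), left_eye = c(-4, -79), right_eye = c(4, -79),
    left_ear = c(-9, -76), right_ear = c(9, -76),
    left_shoulder = c(-18, -55), right_shoulder = c(18, -55),
    left_elbow = c(-24, -30), right_elbow = c(24, -30),
    left_wrist = c(-26, -5), right_wrist = c(26, -5),
    left_hip = c(-12, 0), right_hip = c(12, 0),
    left_knee = c(-13, 45), right_knee = c(13, 45),
    left_ankle = c(-14, 90), right_ankle = c(14, 90)
  )
  colnames(m) <- c("x", "y")
  m
}

# rotate offsets (degrees, clockwise in image coordinates)
rotate_template <- function(m, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  out <- m %*% t(R)
  colnames(out) <- c("x", "y")
  out
}

#' Synthetic motion configuration
#'
#' Describes a deterministic generator of labeled 17-joint pose sequences.
#' Each of the 12 activity classes follows an analytic archetype built from
#' an upright (or reclined) posture template plus class-specific
#' kinematics: periodic limb oscillation for walking, a vertical crouch
#' cycle for picking up an object, whole-body vertical bounce for jumping,
#' small postural sway for standing/sitting/laying, a random-drift posture
#' for the unknown class, and — for the five fall classes — a monotone
#' 1-second descent from upright to lying (direction and trajectory differ
#' per fall type), so the head's image y-coordinate increases over the
#' sequence. Falls end in a reclined posture deliberately similar to the
#' laying class, which is what makes minority fall classes hard when they
#' are under-represented.
#'
#' @param counts named integer vector: sequences to generate per class id
#'   (`"1"`..`"12"`; absent classes get none).
#' @param fps frames per second (default 18).
#' @param seconds duration of each sequence (default 2.5).
#' @param frame_size image width/height in pixels (default 640 x 480);
#'   coordinates are clipped to it.
#' @param noise_sd Gaussian pixel noise added to every joint coordinate
#'   (default 4, about the keypoint jitter of a good pose estimator at
#'   480p: 0.5-1% of image height; 0 gives noiseless archetypes).
#' @param jitter randomise the subject's anchor position, movement phase
#'   and left/right orientation per sequence (default TRUE). With
#'   `jitter = FALSE` and `noise_sd` near 0 every sequence of a class is
#'   identical, making the classes trivially separable.
#' @param seed integer seed; generation is bit-reproducible.
#' @return A `motion_config` list.
#' @export
motion_config <- function(counts, fps = 18, seconds = 2.5,
                          frame_size = c(640L, 480L), noise_sd = 4,
                          jitter = TRUE, seed = 1L) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no sequences requested")
  cls <- as.integer(names(counts) %||% seq_along(counts))
  if (is.null(names(counts))) names(counts) <- cls
  if (any(cls < 1L | cls > 12L)) stop("class ids must be in 1..12")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(counts = setNames(as.integer(counts), cls),
                 fps = fps, seconds = seconds,
                 frame_size = as.integer(frame_size),
                 noise_sd = noise_sd, jitter = isTRUE(jitter),
                 seed = as.integer(seed)),
            class = "motion_config")
}

# per-class joint offsets at time t (seconds); returns 17 x 2 matrix plus a
# centre trajectory. phase: per-sequence phase offset in [0, 2pi).
archetype_pose <- function(class, t, duration, phase) {
  base <- skeleton_template()
  lying <- rotate_template(base, 90) # head to the right, on the ground
  osc <- function(f, a) a * sin(2 * pi * f * t + phase)
  pose <- base
  centre_dx <- 0; centre_dy <- 0
  limb <- c("left_elbow", "right_elbow", "left_wrist", "right_wrist",
            "left_knee", "right_knee", "left_ankle", "right_ankle")
  if (class %in% 1:5) {
    # fall archetypes: upright for the first 40% of the sequence, then a
    # smooth 1-second descent into a lying posture, then still.
    fall_start <- 0.4 * duration
    fall_dur <- min(1, 0.6 * duration)
    prog <- min(max((t - fall_start) / fall_dur, 0), 1)
    s <- prog^2 * (3 - 2 * prog)           # smoothstep descent
    dir <- c(1, 1, -1, 1, -1)[class]       # forward / backward / sideways
    shape <- switch(class,
      `1` = s,                             # hands first: single smooth arc
      `2` = ifelse(s < 0.5, 0.7 * s, 0.35 + 1.3 * (s - 0.5)), # knees: 2 phases
      `3` = s,                             # backward
      `4` = s,                             # sideways
      `5` = 0.8 * s)                       # onto a chair: shallower end
    pose <- (1 - shape) * base + shape * rotate_template(base, dir * 90)
    centre_dy <- shape * 70                # hips drop toward the floor
    centre_dx <- dir * shape * 25
  } else if (class == 6) {                 # walking: limb swing + drift
    pose[limb, "x"] <- pose[limb, "x"] +
      osc(1.6, 12) * c(1, -1, 1, -1, -1, 1, -1, 1)
    pose[c("left_ankle", "right_ankle"), "y"] <-
      pose[c("left_ankle", "right_ankle"), "y"] - abs(osc(1.6, 6))
    centre_dx <- 28 * t
    centre_dy <- osc(3.2, 2)
  } else if (class == 7) {                 # standing: small sway
    centre_dx <- osc(0.4, 2)
  } else if (class == 8) {                 # sitting: folded legs, sway
    pose[c("left_knee", "right_knee"), "y"] <- 5
    pose[c("left_knee", "right_knee"), "x"] <-
      pose[c("left_knee", "right_knee"), "x"] + c(-14, 14)
    pose[c("left_ankle", "right_ankle"), "y"] <- 40
    pose[c("left_ankle", "right_ankle"), "x"] <-
      pose[c("left_ankle", "right_ankle"), "x"] + c(-16, 16)
    centre_dy <- 40 + osc(0.4, 1.5)
  } else if (class == 9) {                 # picking up: periodic deep crouch
    dip <- 0.5 * (1 - cos(2 * pi * t / duration))  # one full bend per sequence
    bend <- rotate_template(base, 0)
    bend[c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
           "left_shoulder", "right_shoulder"), "y"] <-
      bend[c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
             "left_shoulder", "right_shoulder"), "y"] + dip * 55
    bend[c("left_wrist", "right_wrist"), "y"] <-
      bend[c("left_wrist", "right_wrist"), "y"] + dip * 70
    pose <- bend
    centre_dy <- dip * 20
  } else if (class == 10) {                # jumping: whole-body bounce
    centre_dy <- -abs(osc(2.2, 18))
  } else if (class == 11) {                # laying: reclined, tiny sway
    pose <- lying
    pose[, "x"] <- pose[, "x"] + osc(0.3, 2)
    centre_dy <- 70
  } else {                                 # unknown: slow postural drift
    pose <- (1 - 0.3 * sin(phase)) * base
    centre_dx <- osc(0.25, 10)
    centre_dy <- osc(0.18, 8)
  }
  list(pose = pose, centre = c(centre_dx, centre_dy))
}

#' Generate a labeled synthetic pose dataset
#'
#' Produces exactly the per-class sequence counts in the configuration.
#' Each sequence places its archetype at a random anchor inside the frame,
#' draws a random movement phase, advances the archetype at `fps`, adds
#' isotropic Gaussian pixel noise, clips to the frame, and samples
#' detection scores uniformly in `[0.5, 1]` (informative but carrying no
#' class signal). Deterministic given `config$seed`.
#'
#' @param config a [motion_config()].
#' @return List of [pose_sequence()] objects with unique `source` ids of
#'   the form `synth-<class>-<replicate>`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "motion_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  n_frames <- round(config$fps * config$seconds)
  W <- config$frame_size[1]; H <- config$frame_size[2]
  out <- list()
  for (cl in as.integer(names(config$counts))) {
    for (rep_i in seq_len(config$counts[[as.character(cl)]])) {
      if (config$jitter) {
        anchor <- c(runif(1, 0.4 * W, 0.6 * W), runif(1, 0.4 * H, 0.5 * H))
        phase <- runif(1, 0, 2 * pi)
        drift_sign <- sample(c(-1, 1), 1)
      } else {
        anchor <- c(0.5 * W, 0.45 * H)
        phase <- 0
        drift_sign <- 1
      }
      attrs <- matrix(NA_real_, n_frames, N_ATTRIBUTES)
      for (f in seq_len(n_frames)) {
        t <- (f - 1) / config$fps
        ap <- archetype_pose(cl, t, config$seconds, phase)
        xy <- ap$pose
        xy[, "x"] <- xy[, "x"] * drift_sign + anchor[1] +
          drift_sign * ap$centre[1]
        xy[, "y"] <- xy[, "y"] + anchor[2] + ap$centre[2]
        if (config$noise_sd > 0) {
          xy <- xy + matrix(rnorm(34, 0, config$noise_sd), 17, 2)
        }
        xy[, "x"] <- pmin(pmax(xy[, "x"], 0), W)
        xy[, "y"] <- pmin(pmax(xy[, "y"], 0), H)
        scores <- runif(17, 0.5, 1)
        attrs[f, ] <- as.vector(t(cbind(xy, scores)))
      }
      out[[length(out) + 1L]] <- pose_sequence(
        attrs, frame = seq_len(n_frames) - 1L, label = cl,
        source = sprintf("synth-%02d-%04d", cl, rep_i), fps = config$fps)
    }
  }
  out
}

#' Per-class window budgets with configurable imbalance
#'
#' Allocates a total window budget across the 12 classes. `"upfall_like"`
#' reproduces the published class shares of the 207,497-window table
#' (walking-like classes near 19-25%, each fall class below 1%);
#' `"uniform"` splits evenly. Largest-remainder rounding conserves the
#' budget exactly.
#'
#' @param style `"upfall_like"` or `"uniform"`.
#' @param budget total number of windows to allocate (>= 12).
#' @return Named integer vector of per-class window counts summing to
#'   `budget`.
#' @export
imbalance_profile <- function(style = c("upfall_like", "uniform"),
                              budget) {
  style <- match.arg(style)
  budget <- as.integer(budget)
  if (budget < 12L) stop("budget must cover at least one window per class")
  share <- if (style == "uniform") {
    rep(1 / 12, 12)
  } else {
    tab <- upfall_tables()$narrative_windows
    tab$n_windows / sum(tab$n_windows)
  }
  raw <- share * budget
  base <- floor(raw)
  rem <- budget - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), 1:12)
}

#' Convert a window budget into per-class sequence counts
#'
#' Helper linking [imbalance_profile()] (window counts) to
#' [motion_config()] (sequence counts): with sequences of `n_frames`
#' frames and stride `stride`, each sequence yields
#' `floor((n_frames - window_frames)/stride) + 1` windows.
#'
#' @param window_counts named per-class window counts.
#' @param seconds,fps sequence duration and frame rate.
#' @param spec a [window_spec()] (for window length and stride).
#' @return Named per-class sequence counts (ceiling, at least 1 for any
#'   positive window request).
#' @export
sequences_for_windows <- function(window_counts, seconds = 2.5, fps = 18,
                                  spec = window_spec(stride = 2L)) {
  n_frames <- round(fps * seconds)
  per_seq <- (n_frames - spec$window_frames) %/% spec$stride + 1L
  if (per_seq < 1L) stop("sequences shorter than one window")
  counts <- ceiling(window_counts / per_seq)
  setNames(as.integer(counts), names(window_counts))
}
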