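# Procedural articulated-walker simulator.
#
# A 2D stick figure walks in sagittal view across a uniform saturated-green
# chroma background. Joint-angle trajectories follow a sinusoidal base gait
# that each gait type perturbs in its characteristic way; the figure is
# rendered as thick limb capsules plus head/torso ellipses so silhouettes are
# plausible single connected blobs. Every sequence carries its ground-truth
# masks and BODY_25 pose keypoints, which makes the segmentation,
# representation and classification stages testable without any real capture.

#' Gait-type labels in the canonical class order
#'
#' The fixed class ordering used throughout the package (confusion matrices,
#' classifier outputs): scissor, spastic, steppage, normal, propulsive.
#'
#' @return character vector of the five gait types.
#' @export
gait_types <- function() c("scissor", "spastic", "steppage", "normal", "propulsive")

#' BODY_25 keypoint names (0-based index order)
#'
#' Names of the 25 body keypoints in the OpenPose BODY_25 convention; position
#' `i` of the vector is keypoint index `i - 1`.
#'
#' @return character vector of length 25.
#' @export
body25_names <- function() {
  c("Nose", "Neck", "RShoulder", "RElbow", "RWrist", "LShoulder", "LElbow",
    "LWrist", "MidHip", "RHip", "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar", "LBigToe", "LSmallToe", "LHeel",
    "RBigToe", "RSmallToe", "RHeel")
}

# Left/right keypoint index pairs (0-based) swapped when mirroring a pose.
body25_lr_pairs <- function() {
  cbind(c(2, 3, 4, 9, 10, 11, 15, 17, 22, 23, 24),
        c(5, 6, 7, 12, 13, 14, 16, 18, 19, 20, 21))
}

# Run expr with a temporary RNG seeded at `seed`, restoring the caller's
# random stream afterwards. All simulator randomness flows through this.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Configure a synthetic walker
#'
#' Builds a validated walker configuration. Defaults emulate the capture
#' conditions of a studio protocol: 10 fps effective framerate with a
#' 20-frame (2 s) gait cycle, a figure roughly 180 px tall in a 240 px frame,
#' and a saturated green chroma background.
#'
#' @param gait_type one of [gait_types()].
#' @param severity 1 or 2; the four pathological types admit two graded
#'   severities, normal gait only severity 1. Severity 2 scales every
#'   deviation parameter of the type by a fixed factor of 1.6.
#' @param frames_per_cycle gait-cycle period in frames at 10 fps (>= 8).
#' @param n_cycles number of gait cycles to generate.
#' @param direction `"left_to_right"` or `"right_to_left"`.
#' @param frame_height frame height in pixels; width is computed so the
#'   walker never touches the border unless `frame_width` is given.
#' @param frame_width optional frame width in pixels.
#' @param limb_lengths named numeric vector of per-segment lengths in pixels:
#'   `torso`, `upper_arm`, `lower_arm`, `thigh`, `shank`, `foot`.
#' @param jitter_amplitude pixel standard deviation of the additive joint
#'   jitter used by the propulsive gait (erratic shaking).
#' @param seed integer seed for the walker's pseudo-random stream.
#' @return object of class `walker_config`.
#' @export
walker_config <- function(gait_type = "normal", severity = 1L,
                          frames_per_cycle = 20L, n_cycles = 3L,
                          direction = "left_to_right",
                          frame_height = 240L, frame_width = NULL,
                          limb_lengths = c(torso = 55, upper_arm = 32,
                                           lower_arm = 28, thigh = 45,
                                           shank = 45, foot = 18),
                          jitter_amplitude = 1.2, seed = 1L) {
  gait_type <- match.arg(gait_type, gait_types())
  direction <- match.arg(direction, c("left_to_right", "right_to_left"))
  severity <- as.integer(severity)
  if (!severity %in% c(1L, 2L))
    stop("severity must be 1 or 2", call. = FALSE)
  if (gait_type == "normal" && severity != 1L)
    stop("normal gait admits only severity 1", call. = FALSE)
  if (frames_per_cycle < 8L)
    stop("frames_per_cycle must be at least 8", call. = FALSE)
  if (n_cycles < 1L) stop("n_cycles must be positive", call. = FALSE)
  need <- c("torso", "upper_arm", "lower_arm", "thigh", "shank", "foot")
  if (!all(need %in% names(limb_lengths)) || any(limb_lengths[need] <= 0))
    stop("limb_lengths must name positive torso/upper_arm/lower_arm/thigh/shank/foot",
         call. = FALSE)
  cfg <- structure(list(
    gait_type = gait_type, severity = severity,
    frames_per_cycle = as.integer(frames_per_cycle),
    n_cycles = as.integer(n_cycles), direction = direction,
    frame_height = as.integer(frame_height),
    frame_width = if (is.null(frame_width)) NULL else as.integer(frame_width),
    limb_lengths = limb_lengths[need],
    jitter_amplitude = jitter_amplitude, seed = as.integer(seed),
    fps = 10), class = "walker_config")
  cfg$params <- walker_gait_params(cfg)
  if (is.null(cfg$frame_width)) {
    leg <- sum(limb_lengths[c("thigh", "shank")])
    half <- leg * sin(cfg$params$hip_amp) + limb_lengths[["foot"]] +
      0.12 * frame_height
    total <- cfg$params$speed * (frames_per_cycle * n_cycles - 1)
    cfg$frame_width <- as.integer(ceiling(2 * half + total + 2 * 10))
  }
  cfg
}

# Resolve the per-type deviation parameters. Severity 2 multiplies each
# deviation by sev_scale = 1.6; the base (normal) gait has none.
walker_gait_params <- function(cfg) {
  s <- if (cfg$severity == 2L) 1.6 else 1
  L <- cfg$limb_lengths
  p <- list(
    hip_amp = 0.40,            # hip swing amplitude (rad from vertical)
    knee_amp = 0.75,           # swing-phase knee flexion amplitude (rad)
    knee_base = 0.08,          # resting knee flexion (rad)
    arm_amp = 0.45,            # shoulder swing amplitude (rad)
    elbow_flex = 0.35,         # constant elbow flexion (rad)
    torso_pitch = 0.04,        # forward lean (rad)
    foot_drop = 0.10,          # toe-down foot pitch (rad)
    step_scale = 1,            # multiplies stride length
    cadence = 1,               # phase multiplier (doubled cadence = 2)
    circ_legs = integer(0),    # legs with circular-sweep circumduction (1=R,2=L)
    circ_amp = 0,              # circumduction second-harmonic amplitude (rad)
    arm_hold = "none",         # none | right_waist | right_chest | both_chest
    jitter = 0,                # additive joint jitter sd (px)
    bounce = 0.035 * L[["torso"]],
    asym = 0.88)               # left/right knee asymmetry of the base gait
  if (cfg$gait_type == "scissor") {
    p$torso_pitch <- 0.22 * s
    p$step_scale <- max(0.25, 1 - 0.32 * s)
    p$knee_amp <- p$knee_amp * max(0.15, 1 - 0.45 * s)
    p$circ_legs <- c(1L, 2L)
    p$circ_amp <- 0.16 * s
  } else if (cfg$gait_type == "spastic") {
    p$circ_legs <- 1L
    p$circ_amp <- 0.20 * s
    p$arm_hold <- if (cfg$severity == 2L) "right_chest" else "right_waist"
  } else if (cfg$gait_type == "steppage") {
    p$knee_amp <- p$knee_amp * (1 + 0.85 * s)
    p$foot_drop <- 0.10 + 0.32 * s
    p$hip_amp <- 0.40 * (1 + 0.10 * (s - 1))
  } else if (cfg$gait_type == "propulsive") {
    p$torso_pitch <- 0.30 * s
    p$step_scale <- 0.5
    p$cadence <- 2
    p$knee_amp <- p$knee_amp * 0.45
    p$arm_hold <- "both_chest"
    p$jitter <- cfg$jitter_amplitude * s
  }
  leg <- sum(L[c("thigh", "shank")])
  # one step length per half base cycle; cadence-doubled gaits take twice as
  # many (shorter) steps in the same wall-clock cycle
  step <- 2 * leg * sin(p$hip_amp) * p$step_scale
  p$speed <- step * 2 * p$cadence / cfg$frames_per_cycle
  p
}

# Keypoints (25 x 3) and rendering auxiliaries for one frame. `jit` is the
# precomputed jitter matrix for this frame (2 x n_joints) or NULL.
walker_frame <- function(cfg, f, jit = NULL, conf = NULL) {
  p <- cfg$params
  L <- cfg$limb_lengths
  dir <- if (cfg$direction == "left_to_right") 1 else -1
  phase <- 2 * pi * p$cadence * (f - 1) / cfg$frames_per_cycle

  leg <- sum(L[c("thigh", "shank")])
  half <- leg * sin(p$hip_amp) + L[["foot"]] + 0.12 * cfg$frame_height
  x0 <- if (dir > 0) 10 + half else cfg$frame_width - 10 - half
  hip_y0 <- cfg$frame_height - leg - 0.075 * cfg$frame_height

  px <- x0 + dir * p$speed * (f - 1)
  py <- hip_y0 - p$bounce * cos(2 * phase)

  # canonical frame: dx forward (+), dy down (+); image x = px + dir * dx
  pt <- function(dx, dy) c(px + dir * dx, py + dy)

  pitch <- p$torso_pitch
  neck <- pt(L[["torso"]] * sin(pitch), -L[["torso"]] * cos(pitch))
  head_r <- 0.30 * L[["torso"]]
  nose_d <- 0.55 * L[["torso"]]
  nose <- pt(L[["torso"]] * sin(pitch) + nose_d * sin(1.6 * pitch) + 0.18 * head_r,
             -L[["torso"]] * cos(pitch) - nose_d * cos(1.6 * pitch))
  head_c <- pt(L[["torso"]] * sin(pitch) + nose_d * sin(1.6 * pitch),
               -L[["torso"]] * cos(pitch) - nose_d * cos(1.6 * pitch) - 0.2 * head_r)

  leg_chain <- function(side) {            # side 1 = right, 2 = left
    ps <- phase + if (side == 1L) 0 else pi
    hip_amp <- p$hip_amp * if (side == 2L) 1.05 else 1
    th <- hip_amp * sin(ps)
    if (side %in% p$circ_legs) {
      # circumduction: stiff knee plus a second-harmonic forward sweep of the
      # thigh, approximating the circular dragging motion in the sagittal plane
      th <- th + p$circ_amp * sin(2 * ps + 1.1)
      kf <- p$knee_base + 0.25 * p$knee_amp * pmax(0, sin(ps + 0.9))
    } else {
      ka <- p$knee_amp * if (side == 2L) p$asym else 1
      kf <- p$knee_base + ka * pmax(0, sin(ps + 0.9))
    }
    knee <- c(L[["thigh"]] * sin(th), L[["thigh"]] * cos(th))
    sh <- th - kf
    ankle <- knee + c(L[["shank"]] * sin(sh), L[["shank"]] * cos(sh))
    fd <- p$foot_drop * if (side %in% p$circ_legs) 1.4 else 1
    toe <- ankle + c(L[["foot"]] * cos(fd), L[["foot"]] * sin(fd))
    list(knee = pt(knee[1], knee[2]), ankle = pt(ankle[1], ankle[2]),
         toe = pt(toe[1], toe[2]))
  }
  legR <- leg_chain(1L); legL <- leg_chain(2L)

  torso_v <- c(sin(pitch), -cos(pitch))   # hip -> neck unit, canonical
  arm_chain <- function(side) {
    hold <- switch(p$arm_hold,
      none = "swing",
      right_waist = if (side == 1L) "waist" else "swing",
      right_chest = if (side == 1L) "chest" else "swing",
      both_chest = "chest")
    sh0 <- c(L[["torso"]] * sin(pitch), -L[["torso"]] * cos(pitch))
    if (hold == "swing") {
      ps <- phase + pi + if (side == 1L) 0 else pi
      ta <- pitch + p$arm_amp * sin(ps)
      el <- sh0 + c(L[["upper_arm"]] * sin(ta), L[["upper_arm"]] * cos(ta))
      wr <- el + c(L[["lower_arm"]] * sin(ta + p$elbow_flex),
                   L[["lower_arm"]] * cos(ta + p$elbow_flex))
    } else if (hold == "waist") {
      # forearm resting at the waist, upper arm hanging close to the trunk
      wr <- c(0.22 * L[["torso"]], -0.10 * L[["torso"]])
      el <- sh0 + c(0.25 * L[["upper_arm"]], 0.95 * L[["upper_arm"]])
      el <- 0.5 * (el + c(wr[1] - 0.3 * L[["lower_arm"]], wr[2]))
    } else {                               # flexed against the chest
      chest <- 0.60 * sh0                  # 40% of the way neck -> mid-hip
      wr <- chest + c(0.14 * L[["torso"]], 0)
      el <- chest + c(0.05 * L[["torso"]], 0.45 * L[["upper_arm"]])
    }
    list(elbow = pt(el[1], el[2]), wrist = pt(wr[1], wr[2]),
         shoulder = pt(sh0[1], sh0[2]))
  }
  armR <- arm_chain(1L); armL <- arm_chain(2L)

  midhip <- pt(0, 0)
  kp <- matrix(0, 25L, 3L)
  put <- function(idx0, xy, cf = 0.9) kp[idx0 + 1L, ] <<- c(xy, cf)
  put(0L, nose); put(1L, neck)
  put(2L, armR$shoulder); put(3L, armR$elbow); put(4L, armR$wrist)
  put(5L, armL$shoulder); put(6L, armL$elbow); put(7L, armL$wrist)
  put(8L, midhip)
  put(9L, midhip + c(0, 2)); put(10L, legR$knee); put(11L, legR$ankle)
  put(12L, midhip + c(0, 2)); put(13L, legL$knee); put(14L, legL$ankle)
  # facial and foot detail points are not animated: confidence 0
  moving <- c(0:14) + 1L
  if (!is.null(jit)) {
    kp[moving, 1L] <- kp[moving, 1L] + jit[1L, ]
    kp[moving, 2L] <- kp[moving, 2L] + jit[2L, ]
  }
  if (!is.null(conf)) kp[moving, 3L] <- conf
  # keypoint x/y are emitted 0-based, matching the OpenPose pixel convention
  kp[moving, 1:2] <- kp[moving, 1:2] - 1
  list(kp = kp, head_c = head_c, head_r = head_r,
       toeR = legR$toe, toeL = legL$toe, jit = jit)
}

# Render the sprite mask for one frame from its keypoints/auxiliaries.
walker_render_mask <- function(cfg, fr) {
  h <- cfg$frame_height; w <- cfg$frame_width
  t0 <- 0.06 * (0.75 * h)                 # stroke ~6% of figure height
  kp <- fr$kp
  g <- function(idx0) kp[idx0 + 1L, 1:2] + 1  # back to 1-based pixel centers
  seg <- function(a, b) c(a[1], a[2], b[1], b[2])
  limbs <- rbind(
    seg(g(1), g(8)),                       # trunk
    seg(g(2), g(3)), seg(g(3), g(4)),      # right arm
    seg(g(5), g(6)), seg(g(6), g(7)),      # left arm
    seg(g(9), g(10)), seg(g(10), g(11)),   # right leg
    seg(g(12), g(13)), seg(g(13), g(14)),  # left leg
    seg(g(11), fr$toeR), seg(g(14), fr$toeL),
    seg(g(1), g(0)))                       # neck
  widths <- c(1.9 * t0, rep(0.75 * t0, 4), rep(t0, 4), rep(0.8 * t0, 2), 0.7 * t0)
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(limbs)))
    mask <- mask | rasterize_segments(limbs[i, , drop = FALSE], h, w, widths[i])
  mask | rasterize_ellipse(fr$head_c[1], fr$head_c[2], 0.85 * fr$head_r * 1.3,
                           1.15 * fr$head_r * 1.3, h, w)
}

#' Generate one labelled synthetic gait sequence
#'
#' Produces frames (optionally), ground-truth masks and BODY_25 poses for a
#' walker configured by [walker_config()]. The truth mask is by construction
#' exactly the rendered sprite's support. Identical configurations (including
#' the seed) give bit-identical output.
#'
#' @param config a `walker_config`.
#' @param render_frames if `FALSE`, RGB chroma frames are skipped (masks and
#'   poses only); useful when only representations are needed.
#' @return object of class `synthetic_sequence` with elements `frames` (list
#'   of h x w x 3 arrays in \[0,1\], or `NULL`), `masks` (list of 0/1
#'   matrices), `poses` (a `pose_sequence`), `background` (one
#'   background-only RGB frame) and `config`.
#' @export
generate_walker_sequence <- function(config, render_frames = TRUE) {
  stopifnot(inherits(config, "walker_config"))
  n <- config$frames_per_cycle * config$n_cycles
  h <- config$frame_height; w <- config$frame_width
  p <- config$params

  out <- with_seed(config$seed, {
    njoint <- 15L
    jit <- if (p$jitter > 0)
      array(stats::rnorm(2 * njoint * n, 0, p$jitter), c(2L, njoint, n))
    else NULL
    conf <- matrix(stats::runif(njoint * n, 0.6, 1), njoint, n)
    bg <- chroma_background(h, w)
    frames <- if (render_frames) vector("list", n) else NULL
    masks <- vector("list", n)
    kps <- array(0, c(25L, 3L, n))
    for (f in seq_len(n)) {
      fr <- walker_frame(config, f,
                         jit = if (is.null(jit)) NULL else jit[, , f],
                         conf = conf[, f])
      kps[, , f] <- fr$kp
      m <- walker_render_mask(config, fr)
      masks[[f]] <- m * 1L
      if (render_frames) frames[[f]] <- compose_frame(bg, m, f)
    }
    list(frames = frames, masks = masks, kps = kps, bg = bg)
  })

  poses <- structure(list(keypoints = out$kps, width = w, height = h,
                          fps = config$fps), class = "pose_sequence")
  structure(list(frames = out$frames, masks = out$masks, poses = poses,
                 background = out$bg, config = config),
            class = "synthetic_sequence")
}

# Saturated green studio backdrop with small per-pixel noise (hue about one
# third of the hue circle), so HSV histogram segmentation is genuinely
# exercised rather than trivially thresholded.
chroma_background <- function(h, w) {
  base <- grDevices::col2rgb(grDevices::hsv(1 / 3, 0.85, 0.72))[, 1] / 255
  arr <- array(0, c(h, w, 3L))
  for (ch in 1:3)
    arr[, , ch] <- pmin(1, pmax(0, base[ch] + stats::runif(h * w, -0.03, 0.03)))
  arr
}

# Composite the sprite over the background: bluish clothing with mild
# per-pixel variation, far from the green hue band.
compose_frame <- function(bg, mask, f) {
  frame <- bg
  idx <- which(mask)
  cloth <- grDevices::col2rgb(grDevices::hsv(0.60, 0.45, 0.45))[, 1] / 255
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[idx] <- pmin(1, pmax(0, cloth[ch] + stats::runif(length(idx), -0.05, 0.05)))
    frame[, , ch] <- plane
  }
  frame
}

#' Generate a studio-protocol dataset manifest
#'
#' One session contributes 36 sequences: 9 conditions (4 pathological gait
#' types at 2 severities plus normal at severity 1), each walked twice in
#' each of the two directions. 23 sessions therefore total 828 sequences;
#' sessions may revisit subjects, emulating capture on two different days.
#'
#' @param n_sessions number of subject-sessions (>= 1).
#' @param seed integer; permutes the subject assignment.
#' @return `data.frame` with columns `session_id`, `subject_id`, `gait_type`,
#'   `severity`, `direction`, `repetition_index`, `sequence_uri`.
#' @export
generate_manifest <- function(n_sessions, seed = 1L) {
  n_sessions <- as.integer(n_sessions)
  if (is.na(n_sessions) || n_sessions < 1L)
    stop("n_sessions must be a positive integer", call. = FALSE)
  # every 12th session (rounded down) is a repeat visit by an earlier subject,
  # e.g. 23 sessions -> 21 distinct subjects
  n_repeat <- n_sessions %/% 12L
  n_subjects <- n_sessions - n_repeat
  subj <- with_seed(seed, {
    base <- seq_len(n_subjects)
    rep_ids <- if (n_repeat > 0) sample(base, n_repeat) else integer(0)
    c(base, rep_ids)
  })
  conds <- rbind(
    data.frame(gait_type = "normal", severity = 1L),
    expand.grid(gait_type = setdiff(gait_types(), "normal"),
                severity = c(1L, 2L), stringsAsFactors = FALSE))
  rows <- list()
  for (s in seq_len(n_sessions)) {
    for (ci in seq_len(nrow(conds))) {
      for (d in c("left_to_right", "right_to_left")) {
        for (r in 1:2) {
          rows[[length(rows) + 1L]] <- data.frame(
            session_id = s, subject_id = subj[s],
            gait_type = conds$gait_type[ci], severity = conds$severity[ci],
            direction = d, repetition_index = r,
            sequence_uri = sprintf("S%02d/%s_sev%d_%s_rep%d", s,
                                   conds$gait_type[ci], conds$severity[ci],
                                   if (d == "left_to_right") "LR" else "RL", r),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a labelled synthetic energy-image training set
#'
#' Emulates the variability of a multi-subject capture protocol: each
#' sequence draws its own gait-cycle period (16 to 24 frames at 10 fps),
#' body size (limb lengths scaled by 0.92 to 1.08), walking direction
#' (canonicalized before averaging) and — for pathological types — severity
#' level (1 or 2, balanced). Representations are computed from the
#' generator's ground-truth masks (GEI) or poses (SEI).
#'
#' @param n_per_class sequences per gait type.
#' @param seed integer seed; the whole set is a deterministic function of it.
#' @param kind `"GEI"` or `"SEI"`.
#' @param classes gait types to include.
#' @param n_cycles gait cycles per sequence.
#' @param mask_noise fraction of mask pixels flipped by salt-and-pepper
#'   speckle before normalization (emulates a noisier capture domain).
#' @param scale_range range of the per-sequence limb-length scale factor.
#' @return list with `representations` (list of `gait_representation`),
#'   `labels` (character vector) and `subjects` (one synthetic subject id
#'   per sequence, cycling so subjects reappear across classes).
#' @export
synthetic_training_set <- function(n_per_class = 40, seed = 1L, kind = "GEI",
                                   classes = gait_types(), n_cycles = 2L,
                                   mask_noise = 0, scale_range = c(0.92, 1.08)) {
  draws <- with_seed(seed, {
    n <- n_per_class * length(classes)
    data.frame(fpc = sample(16:24, n, replace = TRUE),
               scale = stats::runif(n, scale_range[1], scale_range[2]),
               dir = sample(c("left_to_right", "right_to_left"), n, TRUE),
               sev = sample(1:2, n, TRUE),
               sseed = sample.int(2^30, n))
  })
  reps <- vector("list", nrow(draws))
  labels <- character(nrow(draws))
  subjects <- integer(nrow(draws))
  base_limbs <- c(torso = 55, upper_arm = 32, lower_arm = 28, thigh = 45,
                  shank = 45, foot = 18)
  i <- 0L
  for (cl in classes) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      sev <- if (cl == "normal") 1L else draws$sev[i]
      cfg <- walker_config(cl, severity = sev,
                           frames_per_cycle = draws$fpc[i],
                           n_cycles = n_cycles, direction = draws$dir[i],
                           limb_lengths = base_limbs * draws$scale[i],
                           seed = draws$sseed[i])
      sq <- generate_walker_sequence(cfg, render_frames = FALSE)
      masks <- sq$masks
      if (mask_noise > 0) {
        # speckle the raw masks, then run them through the same cleanup a
        # real segmentation would apply (morphology + largest component)
        masks <- with_seed(draws$sseed[i] + 1L, lapply(masks, function(m) {
          flip <- matrix(stats::runif(length(m)) < mask_noise, nrow(m), ncol(m))
          noisy <- xor(m > 0, flip)
          largest_component(clean_silhouette(noisy)) * 1L
        }))
      }
      src <- if (kind == "GEI") {
        new_silhouette_sequence(masks, fps = 10)
      } else sq$poses
      src <- canonicalize_direction(src, cfg$direction)
      reps[[i]] <- gait_representation(src, kind)
      labels[i] <- cl
      subjects[i] <- k
    }
  }
  list(representations = reps, labels = labels, subjects = subjects)
}
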