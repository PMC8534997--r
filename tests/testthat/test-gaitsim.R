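# Synthetic walker generator: counts, determinism, gait-type contracts,
# silhouette periodicity and manifest layout.

test_that("sequence length, mask size and pose count follow the configuration", {
  sq <- walker_normal()
  expect_length(sq$masks, 60L)
  expect_equal(dim(sq$poses$keypoints), c(25L, 3L, 60L))
  cfg <- sq$config
  for (m in sq$masks[c(1, 30, 60)])
    expect_equal(dim(m), c(cfg$frame_height, cfg$frame_width))
  expect_null(sq$frames)  # masks-only rendering
})

test_that("identical configurations reproduce bit-identical sequences", {
  cfg <- walker_config("steppage", severity = 2L, frames_per_cycle = 8L,
                       n_cycles = 1L, seed = 123L)
  a <- generate_walker_sequence(cfg)
  b <- generate_walker_sequence(cfg)
  expect_identical(a$masks, b$masks)
  expect_identical(a$poses$keypoints, b$poses$keypoints)
  expect_identical(a$frames, b$frames)
})

test_that("severity 2 is rejected for normal gait and severities are validated", {
  expect_error(walker_config("normal", severity = 2L), "severity 1")
  expect_error(walker_config("scissor", severity = 3L), "severity")
  expect_error(walker_config("normal", frames_per_cycle = 4L), "at least 8")
})

test_that("spastic severity 2 pins the right wrist to the chest while the left arm swings", {
  sq <- generate_walker_sequence(
    walker_config("spastic", severity = 2L, frames_per_cycle = 16L,
                  n_cycles = 2L, seed = 3L), render_frames = FALSE)
  kp <- sq$poses$keypoints
  torso_len <- sq$config$limb_lengths[["torso"]]
  chest <- (kp[2, 1:2, ] + kp[9, 1:2, ]) / 2      # between neck and mid-hip
  d_right <- sqrt(colSums((kp[5, 1:2, ] - chest)^2))   # RWrist = index 4
  expect_lt(max(d_right), 0.35 * torso_len)
  # unaffected left wrist swings: horizontal excursion relative to the hip
  lw_rel <- kp[8, 1, ] - kp[9, 1, ]
  expect_gt(diff(range(lw_rel)), 0.5 * torso_len)
})

test_that("every truth mask is a single connected blob and backgrounds stay in the green hue band", {
  sq <- walker_rendered()
  for (f in c(1L, 5L, 10L)) {
    lab <- EBImage::bwlabel(gaitkit:::as_ebimage(sq$masks[[f]]))
    expect_equal(max(lab), 1)
    frame <- sq$frames[[f]]
    bg_idx <- which(sq$masks[[f]] == 0)
    hsv <- gaitkit:::hsv_of_frame(frame)
    expect_true(all(abs(hsv[1L, bg_idx] - 1 / 3) < 0.06))
  }
  # truth mask equals the composited sprite support: foreground pixels differ
  # from the pure background, background pixels equal it
  expect_true(all(sq$frames[[1]][, , 1][sq$masks[[1]] == 0] ==
                    sq$background[, , 1][sq$masks[[1]] == 0]))
})

test_that("pose keypoints number 25 with confidences in [0, 1]", {
  sq <- walker_normal()
  kp <- sq$poses$keypoints
  expect_equal(dim(kp)[1], 25L)
  expect_true(all(kp[, 3, ] >= 0 & kp[, 3, ] <= 1))
  # facial/foot detail points carry zero confidence
  expect_true(all(kp[16:25, 3, ] == 0))
  expect_true(all(kp[1:15, 3, ] > 0))
})

test_that("silhouette bounding-box width is periodic with the gait cycle", {
  for (fpc in c(14L, 20L)) {
    sq <- generate_walker_sequence(
      walker_config("normal", frames_per_cycle = fpc, n_cycles = 4L,
                    seed = 21L), render_frames = FALSE)
    w <- gaitkit:::silhouette_widths(as_silhouettes(sq))
    w <- w - mean(w)
    ac <- stats::acf(w, lag.max = round(1.5 * fpc), plot = FALSE)$acf[, 1, 1]
    lags <- seq_len(round(1.5 * fpc))
    window <- lags[lags >= round(0.6 * fpc)]
    best <- window[which.max(ac[window + 1L])]
    expect_lte(abs(best - fpc), 1L)
  }
})

test_that("manifest layout matches the capture protocol", {
  m1 <- generate_manifest(1L)
  expect_equal(nrow(m1), 36L)
  m2 <- generate_manifest(2L, seed = 4L)
  expect_equal(nrow(m2), 72L)
  for (s in 1:2) {
    ses <- m2[m2$session_id == s, ]
    conds <- unique(ses[, c("gait_type", "severity")])
    expect_equal(nrow(conds), 9L)
    counts <- table(ses$gait_type, ses$severity)
    expect_true(all(counts[counts > 0] == 4L))  # 2 directions x 2 repetitions
    expect_equal(sum(ses$gait_type == "normal"), 4L)
  }
  expect_error(generate_manifest(0L), "positive")
})

test_that("manifest row count scales as 36 per session with subject reuse", {
  for (n in c(3L, 12L, 23L)) {
    m <- generate_manifest(n, seed = 2L)
    expect_equal(nrow(m), 36L * n)
    expect_equal(length(unique(m$subject_id)), n - n %/% 12L)
    expect_true(all(tapply(m$subject_id, m$session_id,
                           function(x) length(unique(x))) == 1L))
  }
})
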