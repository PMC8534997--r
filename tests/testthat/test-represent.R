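# Gait representations: framerate resampling, mirroring, silhouette
# normalization, cycle detection, energy-image averaging and skeleton
# rasterization.

test_that("framerate resampling subsamples at the expected indices", {
  masks <- lapply(1:90, function(i) {
    m <- matrix(0L, 8L, 8L); m[i %% 8 + 1L, ] <- 1L; m
  })
  s30 <- gaitkit:::new_silhouette_sequence(masks, fps = 30)
  s10 <- resample_framerate(s30, 10)
  expect_length(s10$masks, 30L)
  expect_identical(s10$masks, masks[seq(1, 90, by = 3)])
  expect_identical(resample_framerate(s10, 10), s10)

  s25 <- gaitkit:::new_silhouette_sequence(masks[c(1:90, 1:10)], fps = 25)
  out <- resample_framerate(s25, 10)
  # oracle: direct index arithmetic
  want <- round((0:39) * 25 / 10) + 1
  expect_length(out$masks, 40L)
  expect_identical(out$masks, s25$masks[want])
  expect_error(resample_framerate(s10, 30), "upsample")
})

test_that("direction canonicalization mirrors masks and poses exactly once", {
  sq <- walker_normal()
  sil <- as_silhouettes(sq)
  expect_identical(canonicalize_direction(sil, "left_to_right"), sil)
  flipped <- canonicalize_direction(sil, "right_to_left")
  expect_identical(canonicalize_direction(flipped, "right_to_left"), sil)
  expect_identical(flipped$masks[[1]], sil$masks[[1]][, ncol(sil$masks[[1]]):1])

  poses <- sq$poses
  pf <- canonicalize_direction(poses, "right_to_left")
  # the mirrored former left wrist lands on the right-wrist index
  expect_equal(pf$keypoints[5, 1, ], poses$width - 1 - poses$keypoints[8, 1, ])
  expect_equal(pf$keypoints[5, 2, ], poses$keypoints[8, 2, ])
  expect_equal(pf$keypoints[5, 3, ], poses$keypoints[8, 3, ])
  back <- canonicalize_direction(pf, "right_to_left")
  expect_equal(back$keypoints, poses$keypoints)
})

test_that("silhouette normalization crops, scales to height 224 and centers", {
  full <- matrix(1L, 50L, 50L)
  out <- normalize_silhouette(full)
  expect_equal(dim(out), c(224L, 224L))
  expect_true(all(out == 1L))

  rect <- matrix(0L, 150L, 150L)
  rect[26:125, 51:100] <- 1L            # 100 x 50 box
  out <- normalize_silhouette(rect)
  on_cols <- which(colSums(out) > 0)
  expect_equal(length(on_cols), 112L)   # width scales by 224/100
  expect_equal(range(on_cols), c(57L, 168L))
  expect_true(all(out[, on_cols] == 1L))

  single <- matrix(0L, 30L, 30L); single[4L, 9L] <- 1L
  out <- normalize_silhouette(single)   # aspect-preserving: fills the canvas
  expect_equal(dim(out), c(224L, 224L))
  expect_true(all(colSums(out) %in% c(0L, 224L)))
  expect_error(normalize_silhouette(matrix(0L, 5L, 5L)), "empty")
})

test_that("gait cycles are recovered from the silhouette width signal", {
  for (fpc in c(14L, 20L)) {
    sq <- generate_walker_sequence(
      walker_config("normal", frames_per_cycle = fpc, n_cycles = 3L,
                    seed = 31L), render_frames = FALSE)
    cyc <- detect_gait_cycles(as_silhouettes(sq))
    expect_gte(nrow(cyc), 1L)
    lengths <- cyc$end_frame - cyc$start_frame + 1L
    expect_true(all(abs(lengths - fpc) <= 1L))
  }
  # constant width: no cycle found
  flat <- gaitkit:::new_silhouette_sequence(
    replicate(30, { m <- matrix(0L, 20L, 20L); m[5:15, 5:15] <- 1L; m },
              simplify = FALSE))
  expect_equal(nrow(detect_gait_cycles(flat)), 0L)
})

test_that("energy images equal the brute-force per-pixel mean", {
  set.seed(42)
  for (n in c(2L, 8L, 32L)) {
    imgs <- lapply(seq_len(n), function(i)
      matrix(as.integer(stats::runif(224 * 224) > 0.5), 224L, 224L))
    e <- compute_energy_image(imgs, "GEI")
    oracle <- apply(simplify2array(imgs), c(1, 2), mean)
    expect_equal(e$pixels, oracle, tolerance = 1e-15)
    expect_true(all(e$pixels >= 0 & e$pixels <= 1))
    # spot-check a handful of pixels with explicit accumulation loops
    for (p in sample(224 * 224, 5)) {
      acc <- 0
      for (i in seq_len(n)) acc <- acc + imgs[[i]][p]
      expect_equal(e$pixels[p], acc / n)
    }
    # frame order does not matter
    e2 <- compute_energy_image(rev(imgs), "GEI")
    expect_equal(e2$pixels, e$pixels)
  }
  ones <- matrix(1L, 224L, 224L); zeros <- matrix(0L, 224L, 224L)
  expect_true(all(compute_energy_image(list(ones, zeros), "GEI")$pixels == 0.5))
  expect_identical(compute_energy_image(list(ones, ones), "GEI")$pixels + 0,
                   ones + 0)
  expect_error(compute_energy_image(list(), "GEI"), "no images")
})

test_that("a whole-sequence energy image is the frame-weighted mean of tiling cycles", {
  set.seed(3)
  imgs <- lapply(1:8, function(i)
    matrix(as.integer(stats::runif(224 * 224) > 0.5), 224L, 224L))
  whole <- compute_energy_image(imgs, "GEI")
  c1 <- compute_energy_image(imgs[1:3], "GEI", "per_cycle", cycle = c(1, 3))
  c2 <- compute_energy_image(imgs[4:8], "GEI", "per_cycle", cycle = c(4, 8))
  weighted <- (3 * c1$pixels + 5 * c2$pixels) / 8
  expect_equal(whole$pixels, weighted, tolerance = 1e-12)
})

test_that("skeleton rasterization draws exactly the confident limb pairs", {
  kp <- matrix(0, 25L, 3L)
  kp[1, ] <- c(5, 10, 1)    # nose at (5, 10)
  kp[2, ] <- c(15, 10, 1)   # neck at (15, 10)
  img <- rasterize_skeleton(kp, width = 30L, height = 30L, thickness = 3)
  expect_equal(dim(img), c(30L, 30L))
  expect_true(all(img[11L, 7:15] == 1L))        # horizontal bar
  expect_true(all(img[c(5L, 20L), ] == 0L))     # nothing far from it
  # dropping one endpoint's confidence removes the limb
  kp2 <- kp; kp2[1, 3] <- 0.05
  expect_null(rasterize_skeleton(kp2, 30L, 30L))
  expect_null(rasterize_skeleton(matrix(0, 25, 3), 30L, 30L))

  # a full generator pose covers every limb whose endpoints are confident
  sq <- walker_normal()
  pose <- sq$poses$keypoints[, , 5]
  img <- rasterize_skeleton(pose, sq$poses$width, sq$poses$height)
  pairs <- skeleton_limb_pairs() + 1L
  ok <- pose[pairs[, 1], 3] > 0.1 & pose[pairs[, 2], 3] > 0.1
  expect_equal(sum(ok), 14L)   # the moving-limb edges among keypoints 0-14
  for (r in which(ok)) {
    mid <- (pose[pairs[r, 1], 1:2] + pose[pairs[r, 2], 1:2]) / 2 + 1
    y <- round(mid[2]); x <- round(mid[1])
    patch <- img[max(1, y - 2):min(nrow(img), y + 2),
                 max(1, x - 2):min(ncol(img), x + 2)]
    expect_gt(sum(patch), 0)
  }
})

test_that("the SEI shares the GEI averaging path applied to rasterized skeletons", {
  sq <- generate_walker_sequence(
    walker_config("normal", frames_per_cycle = 10L, n_cycles = 1L, seed = 9L),
    render_frames = FALSE)
  sei <- gait_representation(sq$poses, "SEI")
  manual <- lapply(1:10, function(f)
    normalize_silhouette(rasterize_skeleton(sq$poses$keypoints[, , f],
                                            sq$poses$width, sq$poses$height)))
  expect_equal(sei$pixels, compute_energy_image(manual, "SEI")$pixels)
  expect_equal(sei$kind, "SEI")
})

test_that("per-cycle representations follow detected cycles", {
  sq <- walker_normal()
  sil <- as_silhouettes(sq)
  cycles <- detect_gait_cycles(sil)
  reps <- gait_representation(sil, "GEI", scope = "per_cycle", cycles = cycles)
  expect_length(reps, nrow(cycles))
  for (r in reps) {
    expect_equal(r$scope, "per_cycle")
    expect_equal(dim(r$pixels), c(224L, 224L))
  }
})
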