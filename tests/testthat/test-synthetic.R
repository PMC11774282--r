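# Synthetic face generator: determinism, geometry, labels, fluorescence.

test_that("frame generation is deterministic and keypoints sit on the pupil", {
  p <- clean_params(radius = 10)
  a <- generate_frame(p, 3L)
  b <- generate_frame(p, 3L)
  expect_identical(a, b)
  kp <- a$keypoints
  # pupil3/pupil4 are the horizontal extrema: distance 2 * radius
  expect_equal(sqrt(sum((kp["pupil3", ] - kp["pupil4", ])^2)), 20)
  expect_equal(sqrt(sum((kp["pupil1", ] - kp["pupil2", ])^2)), 20)
  # all keypoints inside the frame
  expect_true(all(kp >= 0 & kp < p$image_size))
})

test_that("rasterised pupil extrema coincide with stored keypoints (noiseless)", {
  for (g in 0:2) {
    p <- scene_params(pain_grade = g, noise_sigma = 0, wipe_rate = 0, seed = g + 1)
    fr <- generate_frame(p, 0L)
    pup <- which(fr$image == 0.08, arr.ind = TRUE)  # row = y + 1, col = x + 1
    expect_lte(abs(min(pup[, 2]) - 1 - fr$keypoints["pupil3", "x"]), 0.5)
    expect_lte(abs(max(pup[, 2]) - 1 - fr$keypoints["pupil4", "x"]), 0.5)
    expect_lte(abs(min(pup[, 1]) - 1 - fr$keypoints["pupil1", "y"]), 0.5)
    expect_lte(abs(max(pup[, 1]) - 1 - fr$keypoints["pupil2", "y"]), 0.5)
  }
})

test_that("parameter validation rejects impossible scenes", {
  expect_error(scene_params(image_size = 16), "image_size")
  expect_error(scene_params(pupil_radius_mean = 60), "too small")
  expect_error(scene_params(pain_grade = 5), "pain_grade")
})

test_that("clips have the requested length and respect the wipe process", {
  p <- scene_params(pain_grade = 1, seed = 4)
  cl <- generate_clip(p, 16L)
  expect_equal(dim(cl$frames)[1], 16L)
  expect_length(cl$keypoints, 16L)
  expect_equal(cl$grade, 1L)
  # no wipes: forelimb keypoints stationary
  p0 <- clean_params(grade = 2)
  cl0 <- generate_clip(p0, 8L)
  limb <- t(sapply(cl0$keypoints, function(k) k["limb1", ]))
  expect_equal(max(apply(limb, 2, function(v) diff(range(v)))), 0)
  # different seeds: same grade, different wipe times
  pa <- scene_params(pain_grade = 2, seed = 1)
  pb <- scene_params(pain_grade = 2, seed = 2)
  ca <- generate_clip(pa, 12L); cb <- generate_clip(pb, 12L)
  expect_equal(ca$grade, cb$grade)
  expect_false(identical(ca$wipe_starts, cb$wipe_starts))
})

test_that("datasets are balanced, manifest-deterministic, and label-monotone", {
  d1 <- generate_dataset(10, clip_length = 2L, seed = 9)
  expect_equal(as.vector(table(d1$manifest$grade)), c(10L, 10L, 10L))
  d2 <- generate_dataset(10, clip_length = 2L, seed = 9)
  expect_identical(d1$manifest, d2$manifest)
  # monotone structure across >= 100 clips per grade: pupil radius strictly
  # decreasing, wipe-event count strictly increasing with grade
  d <- generate_dataset(100, clip_length = 2L, seed = 33, image_size = 64)
  rad <- vapply(d$clips, function(cl) {
    kp <- cl$keypoints[[1]]
    (kp["pupil4", "x"] - kp["pupil3", "x"]) / 2  # recomputed from annotations
  }, numeric(1))
  wip <- vapply(d$clips, function(cl) cl$n_wipe_events, numeric(1))
  g <- d$manifest$grade
  mean_rad <- tapply(rad, g, mean)
  mean_wip <- tapply(wip, g, mean)
  expect_true(all(diff(mean_rad) < 0))
  expect_true(all(diff(mean_wip) > 0))
})

test_that("clips round-trip through the PNG + CSV writer", {
  dir <- file.path(tempdir(), "clip_out")
  cl <- generate_clip(clean_params(), 3L)
  ann <- write_clip(cl, dir)
  expect_equal(nrow(ann), 3L)
  expect_true(file.exists(file.path(dir, "frame_0000.png")))
  img <- png::readPNG(file.path(dir, "frame_0001.png"))
  expect_equal(dim(img), c(64L, 64L))
  expect_equal(max(abs(img - cl$frames[2, , ])), 0, tolerance = 1 / 255)
  back <- read.csv(file.path(dir, "annotations.csv"))
  expect_equal(back$pupil3_x[1], cl$keypoints[[1]]["pupil3", "x"])
  unlink(dir, recursive = TRUE)
})

test_that("fluorescence stacks have disjoint masks and invertible structure", {
  sig <- c(rep(0, 8), rep(5, 4), rep(0, 8))
  st <- generate_fluorescence_stack(100, sig, ring_contamination = 2,
                                    noise_sigma = 0)
  m <- st$masks
  expect_false(any(m$roi & m$ring) || any(m$roi & m$background) ||
                 any(m$ring & m$background))
  # null signal: dFF identically zero
  st0 <- generate_fluorescence_stack(50, rep(0, 10))
  tr0 <- extract_traces(st0$stack, st0$masks)
  r0 <- compute_dff(fluorescence_record(tr0$F_raw, tr0$F_ring, tr0$F_b))
  expect_equal(r0$dff, rep(0, 10))
  # square pulse recovered up to normalisation (baseline window = rest)
  tr <- extract_traces(st$stack, st$masks)
  rec <- compute_dff(fluorescence_record(tr$F_raw, tr$F_ring, tr$F_b),
                     baseline_window = 1:8)
  shape <- rec$dff - rec$dff[1]
  expect_equal(shape / max(shape), sig / max(sig), tolerance = 1e-9)
  # overlapping masks are rejected
  bad <- st$masks
  bad$ring[m$roi] <- TRUE
  expect_error(generate_fluorescence_stack(10, rep(1, 3), masks = bad),
               "disjoint")
  expect_error(generate_fluorescence_stack(-1, rep(1, 3)), ">= 0")
})
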