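# Keypoint network: score-map targets, readout, shapes, training.

test_that("a radius-5 disk target at a map-cell centre has exactly 81 cells", {
  cfg <- kpnet_config(input_size = 64, backbone = "small_residual",
                      backbone_stride = 2)  # map stride 1
  expect_equal(cfg$map_size, 64L)
  kp <- matrix(NA_real_, 8, 2, dimnames = list(keypoint_names(),
                                               c("x", "y")))
  kp["pupil1", ] <- c(32.5, 32.5)  # exactly on a cell centre
  tgt <- make_target(kp, cfg)
  # independent lattice enumeration: dx^2 + dy^2 <= 25
  lattice <- sum(outer((-6:6)^2, (-6:6)^2, "+") <= 25)
  expect_equal(sum(tgt[, , 1]), lattice)
  expect_equal(lattice, 81)
  # invisible keypoints give all-zero maps
  expect_equal(sum(tgt[, , 2:8]), 0)
  # radius 0 degenerates to the single centre cell
  cfg0 <- kpnet_config(input_size = 64, backbone = "small_residual",
                       backbone_stride = 2, positive_radius = 0)
  tgt0 <- make_target(kp, cfg0)
  expect_equal(sum(tgt0[, , 1]), 1)
  expect_equal(which(tgt0[, , 1] == 1, arr.ind = TRUE),
               matrix(c(33L, 33L), 1), ignore_attr = TRUE)
})

test_that("shifting a keypoint shifts its positive region identically", {
  cfg <- kpnet_config(input_size = 64, backbone = "small_residual",
                      backbone_stride = 2)
  kp <- matrix(NA_real_, 8, 2, dimnames = list(keypoint_names(),
                                               c("x", "y")))
  kp["limb2", ] <- c(20.5, 30.5)
  base <- which(make_target(kp, cfg)[, , 6] == 1, arr.ind = TRUE)
  kp2 <- kp
  kp2["limb2", ] <- kp["limb2", ] + c(5, -3)  # (dx, dy)
  shifted <- which(make_target(kp2, cfg)[, , 6] == 1, arr.ind = TRUE)
  expect_equal(shifted[, "row"], base[, "row"] - 3L)  # rows = y
  expect_equal(shifted[, "col"], base[, "col"] + 5L)
})

test_that("readout maps peak cells to input coordinates by cell centres", {
  maps <- array(0, c(32, 32, 8))
  maps[11, 21, 1] <- 1  # 0-based cell (10, 20)
  out <- readout(maps, map_stride = 8)
  expect_equal(unname(out[1, ]), c(20 * 8 + 4, 10 * 8 + 4))  # (164, 84)
  # constant maps resolve to cell (0, 0) by the (y, x) tie rule
  expect_equal(unname(out[2, ]), c(4, 4))
  # soft readout of a symmetric two-cell peak lands between the cells
  maps2 <- array(0, c(32, 32, 8))
  maps2[11, 21, 1] <- 1; maps2[11, 22, 1] <- 1
  soft <- readout(maps2, map_stride = 8, method = "soft", beta = 50)
  expect_equal(unname(soft[1, 1]), 20.5 * 8 + 4, tolerance = 1e-6)
})

test_that("readout inverts make_target within the stride tolerance", {
  cfg <- kpnet_config(input_size = 64, backbone = "small_residual",
                      backbone_stride = 4)  # map stride 2
  withr::with_seed(3, {
    for (r in 1:10) {
      kp <- matrix(runif(16, 10, 54), 8, 2,
                   dimnames = list(keypoint_names(), c("x", "y")))
      rec <- readout(make_target(kp, cfg), cfg$map_stride)
      err <- sqrt(rowSums((rec - kp)^2))
      expect_lt(max(err), cfg$map_stride / 2 + cfg$positive_radius + 1e-9)
    }
  })
})

test_that("forward passes follow the stride arithmetic of the backbone", {
  # reduced backbone, stride 16, input 128 -> 8 maps of 16 x 16
  m128 <- kpnet(kpnet_config(input_size = 128, backbone = "small_residual",
                             backbone_stride = 16, seed = 2))
  fr <- matrix(runif(128 * 128), 128, 128)
  maps <- kpnet_forward(m128, fr)
  expect_equal(dim(maps), c(16L, 16L, 8L))
  expect_true(all(maps >= 0 & maps <= 1))
  expect_error(kpnet_forward(m128, matrix(0, 64, 64)), "must be 128 x 128")
  # zeroed head weights give constant score maps
  m0 <- m128
  m0$params$head$w[] <- 0
  m0$params$head$b[] <- 0
  maps0 <- kpnet_forward(m0, fr)
  expect_equal(max(apply(maps0, 3, function(mm) diff(range(mm)))), 0)
  # determinism
  expect_identical(maps, kpnet_forward(m128, fr))
})

test_that("the full-scale backbone reproduces its shape ladder end to end", {
  # run the ResNet-50 geometry at a reduced input; stage sides follow
  # input / {2, 4, 8, 16, 16} and the score maps input / 8
  m <- kpnet(kpnet_config(input_size = 64, seed = 1))
  sh <- kpnet_shapes(m$config)
  expect_equal(sh$side[sh$layer == "stem_conv"], 32)
  expect_equal(sh$side[sh$layer == "block_16"], 4)
  expect_equal(sh$channels[sh$layer == "block_16"], 2048)
  maps <- kpnet_forward(m, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(maps), c(8L, 8L, 8L))
  expect_equal(dim(maps)[1], sh$side[sh$layer == "score_maps"])
})

test_that("training reduces the loss, is seed-reproducible, and lr=0 freezes", {
  ds <- make_kp_dataset(4, seed = 8, size = 32L)
  cfg <- kpnet_config(input_size = 32, backbone = "small_residual",
                      backbone_stride = 4, iters = 30, batch = 4,
                      lr = 0.05, seed = 11)
  fit <- train_kpnet(ds$frames, ds$keypoints, cfg)
  expect_lt(tail(fit$loss, 1), fit$loss[1])
  cfg5 <- cfg; cfg5$iters <- 5L
  f1 <- train_kpnet(ds$frames, ds$keypoints, cfg5)
  f2 <- train_kpnet(ds$frames, ds$keypoints, cfg5)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$params, f2$params)
  cfg0 <- cfg5; cfg0$lr <- 0; cfg0$momentum <- 0
  base <- kpnet(cfg0)
  f0 <- train_kpnet(ds$frames, ds$keypoints, cfg0)
  expect_identical(f0$params, base$params)
  expect_error(train_kpnet(list(), list(), cfg), "empty")
})

test_that("keypoint errors are Euclidean distances with an RMSE summary", {
  kp <- matrix(runif(16), 8, 2, dimnames = list(keypoint_names(),
                                                c("x", "y")))
  e0 <- keypoint_error(kp, kp)
  expect_equal(unname(e0$distances), rep(0, 8))
  expect_equal(e0$rmse, 0)
  off <- kp
  off["pupil1", ] <- kp["pupil1", ] + c(3, 4)
  expect_equal(unname(keypoint_error(off, kp)$distances["pupil1"]), 5)
  # two points with distances {0, 2} -> RMSE sqrt(2)
  a <- matrix(c(0, 0, 0, 0), 2, 2)
  b <- matrix(c(0, 0, 0, 2), 2, 2)
  expect_equal(keypoint_error(a, b)$rmse, sqrt(2))
  bad <- kp
  rownames(bad)[1] <- "nose"
  expect_error(keypoint_error(bad, kp), "names")
})
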