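# 3-D CNN: configuration contracts, shape oracle, forward, training, sweep.

test_that("the configuration enforces the six-conv / three-pool structure", {
  expect_error(cnn3d_config(channels = c(8, 8, 16)), "six")
  expect_error(cnn3d_config(spatial_kernel = 4), "odd")
  expect_error(cnn3d_config(temporal_depth = 12), "divisible")
  expect_error(cnn3d_config(input_side = 100), "divisible")
  cfg <- cnn3d_config()
  expect_length(cfg$channels, 6L)
  expect_length(cfg$pool_after, 3L)
})

test_that("layer shapes match the closed-form calculator on random configs", {
  withr::with_seed(4, {
    for (r in 1:5) {
      ch <- sample(c(2L, 3L, 4L), 6, replace = TRUE)
      cfg <- cnn3d_config(temporal_depth = 8, input_side = 8 * sample(1:2, 1),
                          channels = ch, spatial_kernel = sample(c(3L, 5L), 1),
                          seed = r)
      model <- cnn3d(cfg)
      clip <- array(runif(cfg$temporal_depth * cfg$input_side^2),
                    c(cfg$temporal_depth, cfg$input_side, cfg$input_side))
      fw <- pf$cnn3d_forward_full(model, clip, keep_cache = TRUE)
      sh <- cnn3d_shapes(cfg)
      conv_rows <- sh[grepl("conv3d", sh$layer), ]
      for (i in 1:6) {
        expect_equal(dim(fw$cache$zs[[i]]),
                     c(conv_rows$t[i], conv_rows$side[i], conv_rows$side[i],
                       conv_rows$channels[i]))
      }
      expect_equal(length(fw$feature), cfg$fc_dim)
      expect_equal(length(fw$logits), cfg$n_classes)
      # flatten length implied by the calculator matches the fc weights
      last_pool <- sh[sh$layer == "maxpool_3", ]
      expect_equal(ncol(model$params$fc$w),
                   last_pool$t * last_pool$side^2 * last_pool$channels)
    }
  })
})

test_that("probabilities are simplex points and zero heads give uniform 1/3", {
  cfg <- small_cnn3d_config()
  model <- cnn3d(cfg)
  withr::with_seed(9, {
    for (r in 1:10) {
      clip <- array(runif(8 * 16 * 16), c(8, 16, 16))
      p <- cnn3d_forward(model, clip)
      expect_equal(sum(p), 1, tolerance = 1e-6)
      expect_true(all(p >= 0))
    }
  })
  m0 <- model
  m0$params$out$w[] <- 0
  m0$params$out$b[] <- 0
  clip <- array(runif(8 * 16 * 16), c(8, 16, 16))
  expect_equal(cnn3d_forward(m0, clip), rep(1 / 3, 3))
  expect_identical(cnn3d_forward(model, clip), cnn3d_forward(model, clip))
  expect_error(cnn3d_forward(model, array(0, c(8, 8, 8))), "shape")
})

test_that("training learns above chance and honours the seed contract", {
  d <- generate_dataset(8, clip_length = 8L, seed = 14)
  clips <- lapply(d$clips, function(cl) pf$clip_for_texture(cl$frames, 16L))
  labels <- d$manifest$grade
  cfg <- small_cnn3d_config()
  cfg$epochs <- 12L
  fit <- train_cnn3d(clips, labels, cfg)
  expect_gt(tail(fit$history$train_acc, 1), 100 / 3)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # determinism: identical history under the same seed
  cfg2 <- cfg; cfg2$epochs <- 2L
  h1 <- train_cnn3d(clips, labels, cfg2)$history
  h2 <- train_cnn3d(clips, labels, cfg2)$history
  expect_identical(h1, h2)
  # lr = 0: parameters unchanged
  cfg0 <- cfg2; cfg0$lr <- 0; cfg0$momentum <- 0; cfg0$epochs <- 1L
  f0 <- train_cnn3d(clips, labels, cfg0)
  expect_identical(f0$params, cnn3d(cfg0)$params)
  # single-class data is rejected
  expect_error(train_cnn3d(clips[1:8], rep(0L, 8), cfg), "two classes")
})

test_that("batch order does not change per-clip predictions", {
  model <- cnn3d(small_cnn3d_config())
  withr::with_seed(2, {
    clips <- lapply(1:5, function(i) array(runif(8 * 16 * 16), c(8, 16, 16)))
  })
  p <- predict(model, clips)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict(model, clips[perm]), p[perm, ])
})

test_that("the sweep reports one seeded row per grid point", {
  d <- generate_dataset(4, clip_length = 8L, seed = 15)
  clips <- lapply(d$clips, function(cl) pf$clip_for_texture(cl$frames, 8L))
  labels <- d$manifest$grade
  cfg <- cnn3d_config(temporal_depth = 8, input_side = 8,
                      channels = c(2, 2, 4, 4, 8, 8), lr = 0.01,
                      batch = 8, epochs = 2, seed = 5)
  tab <- cnn3d_sweep(clips, labels, kernel_sizes = c(3, 5),
                     temporal_depths = 8, config = cfg, reps = 1)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab), c("kernel", "depth", "mean_acc", "sd_acc"))
  expect_true(all(tab$mean_acc >= 0 & tab$mean_acc <= 100))
  tab2 <- cnn3d_sweep(clips, labels, kernel_sizes = 3, temporal_depths = 8,
                      config = cfg, reps = 1)
  expect_equal(tab2$mean_acc, tab$mean_acc[tab$kernel == 3])
  expect_error(cnn3d_sweep(clips, labels, kernel_sizes = integer(0),
                           temporal_depths = 8, config = cfg), "nonempty")
})
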