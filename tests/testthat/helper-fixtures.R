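# Shared fixtures, generated in code at test time.

pf <- asNamespace("painface")

# Small scene with no noise and no wipes: pupil extrema are exact.
clean_params <- function(radius = 8, size = 64L, grade = 0L, seed = 1L) {
  scene_params(image_size = size, pain_grade = grade,
               pupil_radius_mean = radius, wipe_rate = 0,
               noise_sigma = 0, seed = seed)
}

# Scene parameters whose grade information is split across the two
# channels: pupil radius separates NP from MP/HP (a fine geometric cue for
# the keypoint channel), texture amplitude separates HP from NP/MP (a
# coarse contrast cue surviving the texture channel's pooling).
channel_split_params <- function(grade, image_size = 64L) {
  scene_params(image_size = image_size, pain_grade = grade,
               pupil_radius_mean = c(9, 6.5, 6.5)[grade + 1L],
               wipe_rate = 1,
               texture_amplitude = c(0.08, 0.08, 0.22)[grade + 1L],
               noise_sigma = 0.02)
}

# Frame/keypoint training set drawn from short clips so that wipe poses
# (forelimb over the eye) are represented alongside resting frames.
make_kp_dataset <- function(n_per_grade, seed = 1L, size = 64L,
                            noise_sigma = 0, params_fn = NULL,
                            clip_length = 8L) {
  frames <- list(); kps <- list()
  for (g in 0:2) {
    n_clips <- ceiling(n_per_grade / clip_length)
    got <- 0L
    for (k in seq_len(n_clips)) {
      p <- if (is.null(params_fn))
        scene_params(image_size = size, pain_grade = g,
                     noise_sigma = noise_sigma,
                     seed = pf$derive_seed(seed, g, k))
      else {
        pp <- params_fn(g)
        pp$seed <- pf$derive_seed(seed, g, k)
        pp
      }
      cl <- generate_clip(p, clip_length)
      for (t in seq_len(clip_length)) {
        if (got >= n_per_grade) break
        got <- got + 1L
        frames[[length(frames) + 1L]] <- cl$frames[t, , ]
        kps[[length(kps) + 1L]] <- cl$keypoints[[t]]
      }
    }
  }
  list(frames = frames, keypoints = kps)
}

# Reduced-scale configs used across training tests.
small_kp_config <- function(seed = 7L, ...) {
  kpnet_config(input_size = 64L, backbone = "small_residual",
               backbone_stride = 4L, readout = "soft",
               iters = 250L, batch = 8L, lr = 0.05, seed = seed, ...)
}

small_cnn3d_config <- function(seed = 3L, ...) {
  cnn3d_config(temporal_depth = 8L, input_side = 16L,
               channels = c(4L, 4L, 8L, 8L, 16L, 16L),
               lr = 0.01, batch = 16L, epochs = 25L, seed = seed, ...)
}

# Trained reduced-scale keypoint network, built once per test run.
trained_kpnet_cache <- new.env(parent = emptyenv())
get_trained_kpnet <- function() {
  if (is.null(trained_kpnet_cache$model)) {
    ds <- make_kp_dataset(25, seed = 5, params_fn = channel_split_params)
    trained_kpnet_cache$model <-
      train_kpnet(ds$frames, ds$keypoints, small_kp_config(seed = 5L))
  }
  trained_kpnet_cache$model
}

# Channel-split clip dataset shared by the fusion tests.
split_clip_cache <- new.env(parent = emptyenv())
get_split_clips <- function() {
  if (is.null(split_clip_cache$data)) {
    d <- generate_dataset(30, params_by_grade = lapply(0:2, channel_split_params),
                          clip_length = 8L, seed = 21L)
    split_clip_cache$data <- list(
      clips = lapply(d$clips, function(cl) cl$frames),
      labels = d$manifest$grade)
  }
  split_clip_cache$data
}
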