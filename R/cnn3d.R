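# 3-D convolutional texture channel.
#
# Six shape-preserving 3-D convolutions (ReLU), a 2x2x2 max pool after
# blocks 2, 4 and 6, a fully connected layer condensing the final feature
# tensor to `fc_dim` (default 16), and a softmax classifier over the pain
# grades. With the full-scale default (16-frame clips of 512 x 512, channel
# plan 32-32-64-64-128-128) the shape ladder is
# (16,512,512,32)x2 -> (8,256,256,32) -> (8,256,256,64)x2 -> (4,128,128,64)
# -> (4,128,128,128)x2 -> (2,64,64,128) -> fc 16 -> softmax 3.
# `temporal_depth` parameterises the input clip length; convolution kernels
# default to 3 x 3 x 3 and the spatial kernel side is sweepable.

#' Configuration for the 3-D CNN
#'
#' @param temporal_depth Input clip length in frames (default 16; must be
#'   divisible by 8 for the three 2x temporal poolings).
#' @param input_side Frame side in pixels (default 512; divisible by 8).
#' @param in_channels Input channels per frame (1 = grayscale).
#' @param spatial_kernel Odd spatial kernel side h = w (default 3).
#' @param temporal_kernel Odd temporal kernel extent (default 3).
#' @param channels Output channels of the six convolutional layers.
#' @param fc_dim Width of the fully connected feature layer (default 16).
#' @param n_classes Number of output classes (default 3).
#' @param lr Initial SGD learning rate (default 1e-4).
#' @param momentum SGD momentum.
#' @param batch Mini-batch size (default 16).
#' @param epochs Training epochs (default 100).
#' @param split_fraction Train fraction of the internal split (default 0.8).
#' @param seed Integer seed.
#' @return Object of class `cnn3d_config`.
#' @export
cnn3d_config <- function(temporal_depth = 16L, input_side = 512L,
                         in_channels = 1L,
                         spatial_kernel = 3L, temporal_kernel = 3L,
                         channels = c(32L, 32L, 64L, 64L, 128L, 128L),
                         fc_dim = 16L, n_classes = 3L,
                         lr = 1e-4, momentum = 0.9, batch = 16L,
                         epochs = 100L, split_fraction = 0.8, seed = 1L) {
  if (length(channels) != 6L) stop("exactly six convolutional layers")
  if (spatial_kernel %% 2L == 0L || temporal_kernel %% 2L == 0L)
    stop("kernel extents must be odd (shape-preserving same padding)")
  if (temporal_depth %% 8L != 0L)
    stop("temporal_depth must be divisible by 8 (three 2x poolings)")
  if (input_side %% 8L != 0L)
    stop("input_side must be divisible by 8 (three 2x poolings)")
  structure(list(
    temporal_depth = as.integer(temporal_depth),
    input_side = as.integer(input_side),
    in_channels = as.integer(in_channels),
    spatial_kernel = as.integer(spatial_kernel),
    temporal_kernel = as.integer(temporal_kernel),
    channels = as.integer(channels),
    pool_after = c(2L, 4L, 6L),
    fc_dim = as.integer(fc_dim), n_classes = as.integer(n_classes),
    lr = lr, momentum = momentum, batch = as.integer(batch),
    epochs = as.integer(epochs), split_fraction = split_fraction,
    seed = as.integer(seed)
  ), class = "cnn3d_config")
}

#' Per-layer output shapes of the 3-D CNN
#'
#' Closed-form calculator: same-padded convolutions preserve (T, H, W);
#' each max pool halves all three.
#'
#' @param config A [cnn3d_config()].
#' @return data.frame with `layer`, `t`, `side`, `channels`.
#' @export
cnn3d_shapes <- function(config = cnn3d_config()) {
  t <- config$temporal_depth; s <- config$input_side
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv3d_%d", i), t = t, side = s,
      channels = config$channels[i])
    if (i %in% config$pool_after) {
      t <- t %/% 2L; s <- s %/% 2L
      rows[[length(rows) + 1L]] <- data.frame(
        layer = sprintf("maxpool_%d", match(i, config$pool_after)),
        t = t, side = s, channels = config$channels[i])
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(layer = "fc", t = 1L, side = 1L,
                                          channels = config$fc_dim)
  rows[[length(rows) + 1L]] <- data.frame(layer = "softmax", t = 1L,
                                          side = 1L,
                                          channels = config$n_classes)
  do.call(rbind, rows)
}

#' Instantiate the 3-D CNN
#'
#' @param config A [cnn3d_config()].
#' @return Object of class `cnn3d` (untrained).
#' @export
cnn3d <- function(config = cnn3d_config()) {
  kt <- config$temporal_kernel; ks <- config$spatial_kernel
  flat <- (config$temporal_depth %/% 8L) * (config$input_side %/% 8L)^2 *
    config$channels[6]
  params <- with_seed(derive_seed(config$seed, 31L), {
    cin <- config$in_channels
    convs <- vector("list", 6L)
    for (i in 1:6) {
      cout <- config$channels[i]
      fan_in <- kt * ks * ks * cin
      convs[[i]] <- list(w = init_weight(c(kt, ks, ks, cin, cout), fan_in),
                         b = numeric(cout))
      cin <- cout
    }
    list(convs = convs,
         fc = list(w = init_weight(c(config$fc_dim, flat), flat),
                   b = numeric(config$fc_dim)),
         out = list(w = init_weight(c(config$n_classes, config$fc_dim),
                                    config$fc_dim),
                    b = numeric(config$n_classes)))
  })
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL),
            class = "cnn3d")
}

# Forward pass through the convolutional trunk and fc layer.
# clip: (T, H, W) or (T, H, W, C) array. Returns logits, fc feature and
# caches for the backward pass.
cnn3d_forward_full <- function(model, clip, keep_cache = FALSE) {
  cfg <- model$config
  if (length(dim(clip)) == 3L) dim(clip) <- c(dim(clip), 1L)
  if (dim(clip)[1] != cfg$temporal_depth || dim(clip)[2] != cfg$input_side ||
      dim(clip)[3] != cfg$input_side || dim(clip)[4] != cfg$in_channels)
    stop(sprintf("clip shape (%s) does not match config (%d, %d, %d, %d)",
                 paste(dim(clip), collapse = ", "), cfg$temporal_depth,
                 cfg$input_side, cfg$input_side, cfg$in_channels))
  pad_t <- (cfg$temporal_kernel - 1L) %/% 2L
  pad_s <- (cfg$spatial_kernel - 1L) %/% 2L
  h <- clip
  caches <- list(inputs = vector("list", 6L), zs = vector("list", 6L),
                 pools = list())
  for (i in 1:6) {
    if (keep_cache) caches$inputs[[i]] <- h
    z <- conv3d(h, model$params$convs[[i]]$w, model$params$convs[[i]]$b,
                1L, pad_t, pad_s)
    if (keep_cache) caches$zs[[i]] <- z
    h <- relu(z)
    if (i %in% cfg$pool_after) {
      pl <- maxpool3d(h)
      if (keep_cache)
        caches$pools[[as.character(i)]] <- list(argmax = pl$argmax,
                                                xdim = dim(h))
      h <- pl$out
    }
  }
  flat <- as.vector(h)
  if (keep_cache) caches$flat <- flat
  if (keep_cache) caches$hdim <- dim(h)
  zfc <- as.vector(model$params$fc$w %*% flat) + model$params$fc$b
  feat <- relu(zfc)
  if (keep_cache) { caches$zfc <- zfc; caches$feat <- feat }
  logits <- as.vector(model$params$out$w %*% feat) + model$params$out$b
  list(logits = logits, feature = feat, cache = if (keep_cache) caches)
}

# Backward from dlogits (and optionally an extra gradient on the fc
# feature, used by the fused classifier). Returns grads for convs/fc/out.
cnn3d_backward <- function(model, dlogits, cache, dfeat_extra = NULL) {
  cfg <- model$config
  pad_t <- (cfg$temporal_kernel - 1L) %/% 2L
  pad_s <- (cfg$spatial_kernel - 1L) %/% 2L
  grads <- list(convs = vector("list", 6L))
  if (!is.null(dlogits)) {
    grads$out <- list(w = outer(dlogits, cache$feat), b = dlogits)
    dfeat <- as.vector(t(model$params$out$w) %*% dlogits)
  } else {
    grads$out <- list(w = model$params$out$w * 0, b = model$params$out$b * 0)
    dfeat <- numeric(cfg$fc_dim)
  }
  if (!is.null(dfeat_extra)) dfeat <- dfeat + dfeat_extra
  dzfc <- dfeat * (cache$zfc > 0)
  grads$fc <- list(w = outer(dzfc, cache$flat), b = dzfc)
  dflat <- as.vector(t(model$params$fc$w) %*% dzfc)
  d <- array(dflat, cache$hdim)
  for (i in 6:1) {
    if (i %in% cfg$pool_after) {
      pc <- cache$pools[[as.character(i)]]
      d <- maxpool3d_grad(d, pc$argmax, pc$xdim)
    }
    d <- relu_grad(d, cache$zs[[i]])
    g <- conv3d_grad(cache$inputs[[i]], model$params$convs[[i]]$w, d, 1L,
                     pad_t, pad_s)
    grads$convs[[i]] <- list(w = g$dw, b = g$db)
    d <- g$dx
  }
  # element order must match the parameter list for the SGD update
  list(convs = grads$convs, fc = grads$fc, out = grads$out)
}

#' Class probabilities for a clip
#'
#' @param model A `cnn3d`.
#' @param clip `(T, H, W)` or `(T, H, W, C)` array matching the config.
#' @return Probability vector over the classes (sums to 1).
#' @export
cnn3d_forward <- function(model, clip) {
  softmax(cnn3d_forward_full(model, clip)$logits)
}

#' Train the 3-D CNN
#'
#' Seeded SGD with momentum on the categorical cross-entropy, with an
#' internal seeded 80/20 train/test split; history records per-epoch train
#' and test loss and accuracy.
#'
#' @param clips List of clip arrays.
#' @param labels Integer labels (0-based grades).
#' @param config A [cnn3d_config()].
#' @param model Optional `cnn3d` to continue training (warm start).
#' @param split Optional precomputed split (list with `train_idx`,
#'   `test_idx`), e.g. to share one split across model variants.
#' @return A trained `cnn3d` with a `history` data.frame.
#' @export
train_cnn3d <- function(clips, labels, config = cnn3d_config(),
                        model = NULL, split = NULL) {
  if (length(clips) != length(labels)) stop("clips/labels length mismatch")
  if (length(unique(labels)) < 2L)
    stop("training requires at least two classes")
  if (is.null(model)) model <- cnn3d(config) else config <- model$config
  sp <- if (!is.null(split)) list(train_idx = split$train_idx,
                                  test_idx = split$test_idx)
  else split_train_test(seq_along(clips), config$split_fraction,
                        derive_seed(config$seed, 41L))
  tr <- sp$train_idx; te <- sp$test_idx
  vel <- zero_like(model$params)
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 42L, ep),
                     sample(tr))
    ep_loss <- 0; ep_correct <- 0
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch - 1L, length(ord))]
      grads <- NULL
      for (b in idx) {
        fw <- cnn3d_forward_full(model, clips[[b]], keep_cache = TRUE)
        l <- ce_with_logits(fw$logits, labels[b])
        ep_loss <- ep_loss + l$loss
        ep_correct <- ep_correct + (which.max(l$prob) - 1L == labels[b])
        g <- cnn3d_backward(model, l$dlogits, fw$cache)
        grads <- if (is.null(grads)) g else accum_grads(grads, g)
      }
      grads <- scale_grads(grads, 1 / length(idx))
      stp <- sgd_step(model$params, grads, vel, config$lr, config$momentum)
      model$params <- stp$params
      vel <- stp$vel
      i <- i + config$batch
    }
    te_eval <- evaluate_cnn3d(model, clips[te], labels[te])
    hist[[ep]] <- data.frame(
      epoch = ep,
      train_loss = ep_loss / length(ord),
      train_acc = 100 * ep_correct / length(ord),
      test_loss = te_eval$loss, test_acc = te_eval$accuracy)
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model$split <- sp
  model
}

evaluate_cnn3d <- function(model, clips, labels) {
  if (length(clips) == 0L) return(list(loss = NA_real_, accuracy = NA_real_))
  loss <- 0; correct <- 0
  for (i in seq_along(clips)) {
    fw <- cnn3d_forward_full(model, clips[[i]])
    l <- ce_with_logits(fw$logits, labels[i])
    loss <- loss + l$loss
    correct <- correct + (which.max(l$prob) - 1L == labels[i])
  }
  list(loss = loss / length(clips), accuracy = 100 * correct / length(clips))
}

#' Predict from a trained 3-D CNN
#'
#' @param object A `cnn3d`.
#' @param clips A clip array or list of clip arrays.
#' @param type `"prob"` (default), `"class"` or `"feature"` (the fc
#'   vector fed to the fused classifier).
#' @param ... Unused.
#' @return Vector / matrix of the requested outputs.
#' @export
predict.cnn3d <- function(object, clips, type = c("prob", "class", "feature"),
                          ...) {
  type <- match.arg(type)
  one <- function(cl) {
    fw <- cnn3d_forward_full(object, cl)
    switch(type,
           prob = softmax(fw$logits),
           class = which.max(fw$logits) - 1L,
           feature = fw$feature)
  }
  if (is.array(clips)) return(one(clips))
  res <- lapply(clips, one)
  if (type == "class") unlist(res) else do.call(rbind, res)
}

#' Kernel-size / temporal-depth accuracy sweep
#'
#' Trains one model per grid point (seeded), repeating `reps` times with
#' derived seeds, and reports the mean and sd of the held-out accuracy —
#' the experiment design behind spatial-kernel and temporal-depth
#' comparisons. Clips longer than a grid's temporal depth are centre-cropped
#' in time.
#'
#' @param clips List of clip arrays (length >= max depth).
#' @param labels Integer labels.
#' @param kernel_sizes Odd spatial kernel sides to try.
#' @param temporal_depths Clip lengths to try.
#' @param config Base [cnn3d_config()].
#' @param reps Repetitions per grid point (default 3).
#' @return data.frame with `kernel`, `depth`, `mean_acc`, `sd_acc`.
#' @export
cnn3d_sweep <- function(clips, labels, kernel_sizes = c(3L),
                        temporal_depths = c(16L), config = cnn3d_config(),
                        reps = 3L) {
  if (length(kernel_sizes) == 0L || length(temporal_depths) == 0L)
    stop("sweep grids must be nonempty")
  rows <- list()
  for (k in kernel_sizes) {
    for (d in temporal_depths) {
      accs <- numeric(reps)
      for (r in seq_len(reps)) {
        cfg <- config
        cfg$spatial_kernel <- as.integer(k)
        cfg$temporal_depth <- as.integer(d)
        cfg$seed <- derive_seed(config$seed, k, d, r)
        sub <- lapply(clips, function(cl) {
          Tn <- dim(cl)[1]
          if (Tn < d) stop("clips shorter than requested temporal depth")
          start <- (Tn - d) %/% 2L
          if (length(dim(cl)) == 3L) cl[start + seq_len(d), , , drop = FALSE]
          else cl[start + seq_len(d), , , , drop = FALSE]
        })
        fit <- train_cnn3d(sub, labels, cnn3d_config(
          temporal_depth = d, input_side = cfg$input_side,
          in_channels = cfg$in_channels, spatial_kernel = k,
          temporal_kernel = cfg$temporal_kernel, channels = cfg$channels,
          fc_dim = cfg$fc_dim, n_classes = cfg$n_classes, lr = cfg$lr,
          momentum = cfg$momentum, batch = cfg$batch, epochs = cfg$epochs,
          split_fraction = cfg$split_fraction, seed = cfg$seed))
        accs[r] <- tail(fit$history$test_acc, 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kernel = k, depth = d, mean_acc = mean(accs),
        sd_acc = if (reps > 1) sd(accs) else 0)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.cnn3d <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cnn3d> six 3-D conv layers (%dx%dx%d kernels, channels %s), input (%d, %d, %d)%s\n",
              cfg$temporal_kernel, cfg$spatial_kernel, cfg$spatial_kernel,
              paste(cfg$channels, collapse = "-"), cfg$temporal_depth,
              cfg$input_side, cfg$input_side,
              if (x$trained) sprintf(", trained (%d epochs, test acc %.1f%%)",
                                     nrow(x$history),
                                     tail(x$history$test_acc, 1))
              else ", untrained"))
  invisible(x)
}
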