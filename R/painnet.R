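# Fused two-channel pain classifier.
#
# The trained keypoint network is frozen ("fixed model reuse"): its readout
# coordinates for a designated frame of the clip are flattened into a
# 16-vector, concatenated with the 16-dimensional fc feature of the 3-D
# texture channel into a 1 x 32 fused vector, and a single affine layer +
# softmax produces the three pain-grade probabilities. Training updates the
# 3-D CNN and the fusion head only; the keypoint network's parameters are
# asserted bit-identical before and after.

#' Fuse keypoint coordinates with the texture feature vector
#'
#' Keypoints are flattened in the fixed canonical order
#' (pupil1..4 then limb1..4, x before y per point) and, by default,
#' normalised to \[0, 1\] by the input size so the fusion head is
#' scale-free; `normalize = FALSE` concatenates raw pixel coordinates.
#'
#' @param keypoints `8 x 2` named coordinate matrix.
#' @param texture Numeric feature vector (length `fc_dim`, default 16).
#' @param input_size Input side used for normalisation.
#' @param normalize Normalise coordinates to \[0, 1\] (default TRUE).
#' @return Numeric vector of length `2 * 8 + length(texture)` (32 in the
#'   default configuration).
#' @export
fuse_features <- function(keypoints, texture, input_size, normalize = TRUE) {
  if (nrow(keypoints) != 8L) stop("expected 8 keypoints")
  if (!is.null(rownames(keypoints))) {
    if (!setequal(rownames(keypoints), keypoint_names()))
      stop("keypoint names do not match the canonical set")
    keypoints <- keypoints[keypoint_names(), , drop = FALSE]
  }
  kv <- as.vector(t(keypoints[, 1:2]))  # x1 y1 x2 y2 ...
  if (normalize) kv <- kv / input_size
  c(kv, as.numeric(texture))
}

#' Configuration for the fused classifier
#'
#' @param cnn3d_config The texture-channel [cnn3d_config()].
#' @param keypoint_frame Which frame of the clip feeds the keypoint
#'   channel: `"last"` (default) or `"mean"` (keypoint vectors averaged
#'   over all frames).
#' @param normalize_keypoints Normalise coordinates before fusion
#'   (default TRUE).
#' @param lr,momentum,epochs,batch SGD hyperparameters of the joint
#'   minibatch phase (default lr 1e-4, the texture channel's initial
#'   rate; the pre-trained head makes the fused loss surface steep, so
#'   the joint fine-tuning must move slowly).
#' @param head_lr Learning rate of the full-batch head pre-training
#'   (default 1): fitting the affine head on the frozen fused features is
#'   a convex problem, and the small normalised coordinate contrasts need
#'   large steps to be exploited.
#' @param head_warmup_epochs Full-batch epochs of head-only pre-training
#'   on the initial fused features before the joint minibatch phase
#'   (default 500); lets the head settle on the reused texture features
#'   before gradients flow back into the texture trunk.
#' @param clip_norm Global gradient-norm ceiling of the joint phase
#'   (default 0.5); the pre-trained head can make the fused loss surface
#'   steep, and clipping keeps the fine-tuning steps bounded.
#' @param split_fraction Train fraction of the internal split.
#' @param seed Integer seed.
#' @return Object of class `painnet_config`.
#' @export
painnet_config <- function(cnn3d_config = painface::cnn3d_config(),
                           keypoint_frame = c("last", "mean"),
                           normalize_keypoints = TRUE,
                           lr = 1e-4, momentum = 0.9, epochs = 30L,
                           batch = 16L, head_lr = 1,
                           head_warmup_epochs = 500L, clip_norm = 0.5,
                           split_fraction = 0.8, seed = 1L) {
  structure(list(
    cnn3d = cnn3d_config,
    keypoint_frame = match.arg(keypoint_frame),
    normalize_keypoints = normalize_keypoints,
    lr = lr, head_lr = head_lr, momentum = momentum,
    epochs = as.integer(epochs), batch = as.integer(batch),
    clip_norm = clip_norm,
    head_warmup_epochs = as.integer(head_warmup_epochs),
    split_fraction = split_fraction, seed = as.integer(seed)
  ), class = "painnet_config")
}

# Keypoint vector of a clip under the frozen keypoint channel.
clip_keypoint_vector <- function(kp_model, clip_frames, config) {
  Tn <- dim(clip_frames)[1]
  frames <- if (config$keypoint_frame == "last") Tn else seq_len(Tn)
  vs <- lapply(frames, function(t) {
    kp <- predict(kp_model, clip_frames[t, , ])
    kv <- as.vector(t(kp[keypoint_names(), 1:2]))
    if (config$normalize_keypoints) kv <- kv / kp_model$config$input_size
    kv
  })
  colMeans(do.call(rbind, vs))
}

# Resize clip frames for the texture channel when its input side differs
# from the keypoint-channel side.
clip_for_texture <- function(clip_frames, side) {
  Tn <- dim(clip_frames)[1]
  if (dim(clip_frames)[2] == side) return(clip_frames)
  out <- array(0, c(Tn, side, side))
  for (t in seq_len(Tn))
    out[t, , ] <- crop_and_resize(clip_frames[t, , ], out_size = side)
  out
}

#' Forward pass of the fused classifier
#'
#' @param model A trained `painnet` (or a list with `kpnet`, `cnn3d`,
#'   `head`, `config`).
#' @param clip_frames `(T, S, S)` array at the keypoint-channel resolution.
#' @return List with `prob` (length-3, sums to 1), `grade` (argmax, 0-based)
#'   and `fused` (the 32-vector).
#' @export
painnet_forward <- function(model, clip_frames) {
  kv <- clip_keypoint_vector(model$kpnet, clip_frames, model$config)
  tex_clip <- clip_for_texture(clip_frames, model$cnn3d$config$input_side)
  fw <- cnn3d_forward_full(model$cnn3d, tex_clip)
  fused <- c(kv, fw$feature)
  logits <- as.vector(model$head$w %*% fused) + model$head$b
  p <- softmax(logits)
  list(prob = p, grade = which.max(p) - 1L, fused = fused)
}

#' Train the fused classifier with the keypoint channel frozen
#'
#' The keypoint network must be supplied pre-trained; its parameters are
#' not updated (checksummed before and after as the frozen-reuse
#' contract). The texture channel is initialised fresh (or warm-started
#' from `cnn3d_model`) and trained jointly with the 32 -> 3 fusion head by
#' seeded SGD on the cross-entropy.
#'
#' @param clips List of `(T, S, S)` clip arrays at the keypoint-channel
#'   resolution.
#' @param labels Integer grades (0/1/2).
#' @param kpnet_model A trained [kpnet()].
#' @param config A [painnet_config()].
#' @param cnn3d_model Optional trained [cnn3d()] to warm-start the texture
#'   channel (the cascade reuses the learned texture parameters and keeps
#'   adjusting them).
#' @param split Optional precomputed split (list with `train_idx`,
#'   `test_idx`).
#' @return Object of class `painnet` with training `history` and the
#'   frozen-channel checksums `man_checksum_before` / `_after`.
#' @export
train_painnet <- function(clips, labels, kpnet_model,
                          config = painnet_config(), cnn3d_model = NULL,
                          split = NULL) {
  if (missing(kpnet_model) || is.null(kpnet_model))
    stop("a pre-trained keypoint network is required (fixed model reuse)")
  if (length(clips) != length(labels)) stop("clips/labels length mismatch")
  ck_before <- param_checksum(kpnet_model$params)
  kp_frozen <- kpnet_model$params  # exact copy for the identity assertion

  tex <- if (!is.null(cnn3d_model)) cnn3d_model else cnn3d(config$cnn3d)
  side <- tex$config$input_side

  # frozen channel: precompute per-clip keypoint vectors once
  kvs <- lapply(clips, clip_keypoint_vector, kp_model = kpnet_model,
                config = config)
  tex_clips <- lapply(clips, clip_for_texture, side = side)

  sp <- if (!is.null(split)) list(train_idx = split$train_idx,
                                  test_idx = split$test_idx)
  else split_train_test(seq_along(clips), config$split_fraction,
                        derive_seed(config$seed, 52L))
  tr <- sp$train_idx; te <- sp$test_idx

  # phase 1: full-batch pre-training of the affine head on the fused
  # features of the (warm-started or fresh) texture trunk, which stays
  # fixed here; this is a convex multinomial logistic fit
  feats0 <- lapply(seq_along(clips), function(b)
    c(kvs[[b]], cnn3d_forward_full(tex, tex_clips[[b]])$feature))
  lin <- train_linear_softmax(feats0, labels, tex$config$n_classes,
                              lr = config$head_lr %||% 1,
                              epochs = config$head_warmup_epochs %||% 500L,
                              seed = derive_seed(config$seed, 51L),
                              train_idx = tr)
  head <- list(w = lin$w, b = lin$b)

  vel_tex <- zero_like(tex$params)
  vel_head <- zero_like(head)
  hist <- list()
  model <- structure(list(kpnet = kpnet_model, cnn3d = tex, head = head,
                          config = config), class = "painnet")
  # phase 2: joint minibatch fine-tuning of trunk and head
  for (ep in seq_len(config$epochs)) {
    head_only <- FALSE
    ord <- with_seed(derive_seed(config$seed, 53L, ep), sample(tr))
    ep_loss <- 0; ep_correct <- 0
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch - 1L, length(ord))]
      g_tex <- NULL; g_head <- NULL
      for (b in idx) {
        fw <- cnn3d_forward_full(model$cnn3d, tex_clips[[b]],
                                 keep_cache = !head_only)
        fused <- c(kvs[[b]], fw$feature)
        logits <- as.vector(model$head$w %*% fused) + model$head$b
        l <- ce_with_logits(logits, labels[b])
        ep_loss <- ep_loss + l$loss
        ep_correct <- ep_correct + (which.max(l$prob) - 1L == labels[b])
        gh <- list(w = outer(l$dlogits, fused), b = l$dlogits)
        g_head <- if (is.null(g_head)) gh else accum_grads(g_head, gh)
        if (!head_only) {
          dfused <- as.vector(t(model$head$w) %*% l$dlogits)
          dfeat <- dfused[16L + seq_len(model$cnn3d$config$fc_dim)]
          gt <- cnn3d_backward(model$cnn3d, NULL, fw$cache,
                               dfeat_extra = dfeat)
          g_tex <- if (is.null(g_tex)) gt else accum_grads(g_tex, gt)
        }
      }
      g_head <- clip_grads(scale_grads(g_head, 1 / length(idx)),
                           config$clip_norm %||% Inf)
      s2 <- sgd_step(model$head, g_head, vel_head, config$lr,
                     config$momentum)
      model$head <- s2$params; vel_head <- s2$vel
      if (!head_only) {
        g_tex <- clip_grads(scale_grads(g_tex, 1 / length(idx)),
                            config$clip_norm %||% Inf)
        s1 <- sgd_step(model$cnn3d$params, g_tex, vel_tex, config$lr,
                       config$momentum)
        model$cnn3d$params <- s1$params; vel_tex <- s1$vel
      }
      i <- i + config$batch
    }
    te_acc <- if (length(te)) {
      preds <- vapply(te, function(b) {
        fw <- cnn3d_forward_full(model$cnn3d, tex_clips[[b]])
        fused <- c(kvs[[b]], fw$feature)
        which.max(as.vector(model$head$w %*% fused) + model$head$b) - 1L
      }, integer(1))
      100 * mean(preds == labels[te])
    } else NA_real_
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / length(ord),
                             train_acc = 100 * ep_correct / length(ord),
                             test_acc = te_acc)
  }
  stopifnot(identical(model$kpnet$params, kp_frozen))
  model$history <- do.call(rbind, hist)
  model$split <- sp
  model$man_checksum_before <- ck_before
  model$man_checksum_after <- param_checksum(model$kpnet$params)
  model
}

#' Predict pain grades for clips
#'
#' @param object A trained `painnet`.
#' @param clips A clip array or list of clip arrays at the
#'   keypoint-channel resolution.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... Unused.
#' @return Probability matrix (rows = clips) or integer grades.
#' @export
predict.painnet <- function(object, clips, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.array(clips)) clips <- list(clips)
  res <- lapply(clips, function(cl) painnet_forward(object, cl))
  if (type == "class") vapply(res, `[[`, integer(1), "grade")
  else do.call(rbind, lapply(res, `[[`, "prob"))
}

# Affine + softmax classifier on precomputed feature vectors; used for the
# keypoint-only ablation arm and the fusion-head pre-training (readout
# vector -> affine -> softmax). The fit standardises each feature over the
# training rows (so small-magnitude coordinate contrasts are not
# scale-disadvantaged) and runs full-batch SGD with momentum and a mild L2
# penalty; the scaler is folded back into the returned affine weights, so
# the result is still a plain affine layer over the raw features.
train_linear_softmax <- function(features, labels, n_classes = 3L,
                                 lr = 1, momentum = 0.9, epochs = 1000L,
                                 l2 = 1e-4, seed = 1L, train_idx = NULL) {
  X <- do.call(rbind, features)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(X))
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sd_ <- apply(X[train_idx, , drop = FALSE], 2, sd)
  sd_[sd_ < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  d <- ncol(X)
  par <- with_seed(derive_seed(seed, 61L),
                   list(w = init_weight(c(n_classes, d), d),
                        b = numeric(n_classes)))
  vel <- zero_like(par)
  for (ep in seq_len(epochs)) {
    g <- zero_like(par)
    for (i in train_idx) {
      l <- ce_with_logits(as.vector(par$w %*% Z[i, ]) + par$b, labels[i])
      g <- accum_grads(g, list(w = outer(l$dlogits, Z[i, ]), b = l$dlogits))
    }
    g <- scale_grads(g, 1 / length(train_idx))
    g$w <- g$w + l2 * par$w
    s <- sgd_step(par, g, vel, lr, momentum)
    par <- s$params; vel <- s$vel
  }
  w_raw <- sweep(par$w, 2, sd_, "/")
  b_raw <- par$b - as.vector(w_raw %*% mu)
  structure(list(w = w_raw, b = b_raw), class = "linear_softmax")
}

predict_linear_softmax <- function(model, features) {
  do.call(rbind, lapply(features, function(x)
    softmax(as.vector(model$w %*% x) + model$b)))
}

#' Ablation study: keypoint channel only, texture channel only, fused
#'
#' Trains the three variants on an identical seeded split and reports
#' accuracy, precision, recall, F1 and AUC for each (macro-averaged, on the
#' held-out set). The keypoint-only variant classifies the frozen
#' keypoint-readout vector with an affine + softmax layer; the
#' texture-only variant is the plain 3-D CNN; the fused variant is
#' [train_painnet()].
#'
#' @param clips List of clip arrays at the keypoint-channel resolution.
#' @param labels Integer grades.
#' @param kpnet_model A trained [kpnet()].
#' @param config A [painnet_config()].
#' @return List with `report` (3 x 5 metric data.frame) and the per-variant
#'   `metrics` objects.
#' @export
painnet_ablation <- function(clips, labels, kpnet_model,
                             config = painnet_config()) {
  if (length(clips) == 0L) stop("empty dataset")
  # one seeded split shared by all three variants
  sp <- split_train_test(seq_along(clips), config$split_fraction,
                         derive_seed(config$seed, 52L))
  te <- sp$test_idx
  # keypoint channel only: frozen readout vector -> affine -> softmax
  kvs <- lapply(clips, clip_keypoint_vector, kp_model = kpnet_model,
                config = config)
  lin <- train_linear_softmax(kvs, labels, config$cnn3d$n_classes,
                              seed = config$seed, train_idx = sp$train_idx)
  m_kp <- classification_metrics(labels[te],
                                 predict_linear_softmax(lin, kvs[te]))
  # texture channel only
  cfg3 <- config$cnn3d
  cfg3$seed <- derive_seed(config$seed, 62L)
  tex_clips <- lapply(clips, clip_for_texture, side = cfg3$input_side)
  fit3 <- train_cnn3d(tex_clips, labels, cfg3, split = sp)
  m_tex <- classification_metrics(labels[te], predict(fit3, tex_clips[te]))
  # fused: cascade reuses the learned texture channel, then adjusts it
  # jointly with the fusion head while the keypoint channel stays frozen
  fitp <- train_painnet(clips, labels, kpnet_model, config,
                        cnn3d_model = fit3, split = sp)
  m_fused <- classification_metrics(labels[te], predict(fitp, clips[te]))
  report <- data.frame(
    model = c("keypoint_only", "texture_only", "fused"),
    accuracy = c(m_kp$accuracy, m_tex$accuracy, m_fused$accuracy),
    precision = c(m_kp$precision, m_tex$precision, m_fused$precision),
    recall = c(m_kp$recall, m_tex$recall, m_fused$recall),
    f1 = c(m_kp$f1, m_tex$f1, m_fused$f1),
    auc = c(m_kp$auc, m_tex$auc, m_fused$auc))
  list(report = report,
       metrics = list(keypoint_only = m_kp, texture_only = m_tex,
                      fused = m_fused),
       models = list(keypoint_only = lin, texture_only = fit3,
                     fused = fitp))
}

#' @export
print.painnet <- function(x, ...) {
  cat(sprintf("<painnet> frozen keypoint channel + 3-D texture channel, fused 32 -> %d head\n",
              length(x$head$b)))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final test accuracy %.1f%%\n",
                nrow(x$history), tail(x$history$test_acc, 1)))
  cat(sprintf("  frozen-channel checksum %s (unchanged: %s)\n",
              x$man_checksum_before,
              identical(x$man_checksum_before, x$man_checksum_after)))
  invisible(x)
}
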