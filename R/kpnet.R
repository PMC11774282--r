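# Score-map keypoint network ("keypoint channel").
#
# A residual backbone downsamples the input by `backbone_stride`; eight
# per-keypoint transposed-convolution heads (kernel 4, stride 2, pad 1)
# upsample the final feature map 2x, giving one score map per keypoint at
# stride `backbone_stride / 2` relative to the input. Training minimises
# per-pixel binary cross-entropy against binary disk targets (all map cells
# whose centres lie within `positive_radius` input pixels of the keypoint).
# A readout layer converts each score map to coordinates (arg-max with a
# deterministic tie-break, or soft-argmax).
#
# The full-scale configuration uses a ResNet-50 backbone (bottleneck blocks,
# stage strides 2-2-2-2-1: 512 -> 256 -> 128 -> 64 -> 32 -> 32 with
# 64/256/512/1024/2048 channels, then 64 x 64 x 8 score maps). The reduced
# `small_residual` backbone keeps the same stride pattern with far fewer
# channels and is the practical choice for CPU training.

#' Configuration for the keypoint network
#'
#' @param input_size Input image side in pixels (default 512).
#' @param backbone `"resnet50"` (full-scale) or `"small_residual"`
#'   (reduced channels, same stride pattern).
#' @param backbone_stride Total input-to-feature downsampling factor (a
#'   power of two, default 16; score-map stride is half of it because of
#'   the 2x deconvolutional heads).
#' @param n_keypoints Number of keypoints / score maps (default 8).
#' @param positive_radius Radius in input pixels of the positive disk
#'   around each keypoint in the training targets (default 5, Euclidean).
#' @param in_channels Input channels (1 = infrared grayscale).
#' @param lr,momentum,iters,batch SGD hyperparameters.
#' @param pos_weight Weight of positive pixels in the binary cross-entropy
#'   (offsets the scarcity of positives in the maps).
#' @param readout `"argmax"` (default; ties broken toward the smallest
#'   (y, x)) or `"soft"` (soft-argmax, differentiable).
#' @param soft_beta Inverse temperature for the soft-argmax readout.
#' @param seed Integer seed for initialisation and batch order.
#' @param pretrained_weights Optional path to an RDS file with backbone
#'   parameters to warm-start from; by default initialisation is random
#'   (seeded).
#' @return Object of class `kpnet_config`.
#' @export
kpnet_config <- function(input_size = 512L,
                         backbone = c("resnet50", "small_residual"),
                         backbone_stride = 16L,
                         n_keypoints = 8L,
                         positive_radius = 5,
                         in_channels = 1L,
                         lr = 0.01, momentum = 0.9,
                         iters = 300L, batch = 8L,
                         pos_weight = 20,
                         readout = c("argmax", "soft"),
                         soft_beta = 25,
                         seed = 1L,
                         pretrained_weights = NULL) {
  backbone <- match.arg(backbone)
  readout <- match.arg(readout)
  if (bitwAnd(backbone_stride, backbone_stride - 1L) != 0L || backbone_stride < 2L)
    stop("backbone_stride must be a power of two >= 2")
  if (backbone == "resnet50" && backbone_stride != 16L)
    stop("the resnet50 backbone has a fixed stride of 16")
  if (input_size %% backbone_stride != 0L)
    stop("input_size must be divisible by backbone_stride")
  map_stride <- backbone_stride / 2L
  structure(list(
    input_size = as.integer(input_size), backbone = backbone,
    backbone_stride = as.integer(backbone_stride),
    map_size = as.integer(input_size / map_stride),
    map_stride = as.integer(map_stride),
    n_keypoints = as.integer(n_keypoints),
    positive_radius = positive_radius,
    in_channels = as.integer(in_channels),
    lr = lr, momentum = momentum, iters = as.integer(iters),
    batch = as.integer(batch), pos_weight = pos_weight,
    readout = readout, soft_beta = soft_beta, seed = as.integer(seed),
    pretrained_weights = pretrained_weights
  ), class = "kpnet_config")
}

# ---- architecture plan --------------------------------------------------

# A block is a list of conv specs (k, stride, pad, cin, cout) plus an
# optional 1x1 projection shortcut; the stem is a plain conv.
kpnet_plan <- function(config) {
  cin <- config$in_channels
  if (config$backbone == "resnet50") {
    stem <- list(k = 7L, stride = 2L, pad = 3L, cin = cin, cout = 64L)
    stage_cfg <- list(c(64, 256, 3, 2), c(128, 512, 4, 2),
                      c(256, 1024, 6, 2), c(512, 2048, 3, 1))
    blocks <- list()
    c_prev <- 64L
    for (sc in stage_cfg) {
      mid <- sc[1]; out <- sc[2]; nb <- sc[3]; s <- sc[4]
      for (b in seq_len(nb)) {
        stride <- if (b == 1L) s else 1L
        convs <- list(
          list(k = 1L, stride = stride, pad = 0L, cin = c_prev, cout = mid),
          list(k = 3L, stride = 1L, pad = 1L, cin = mid, cout = mid),
          list(k = 1L, stride = 1L, pad = 0L, cin = mid, cout = out))
        proj <- if (b == 1L)
          list(k = 1L, stride = stride, pad = 0L, cin = c_prev, cout = out)
        else NULL
        blocks[[length(blocks) + 1L]] <- list(convs = convs, proj = proj)
        c_prev <- out
      }
    }
    feat_dim <- 2048L
    list(stem = stem, blocks = blocks, feat = NULL, feat_dim = feat_dim)
  } else {
    stem <- list(k = 5L, stride = 2L, pad = 2L, cin = cin, cout = 16L)
    n_down <- as.integer(log2(config$backbone_stride)) - 1L
    blocks <- list()
    c_prev <- 16L
    widths <- pmin(16L * 2^seq_len(n_down), 64L)
    for (i in seq_len(n_down)) {
      out <- widths[i]
      convs <- list(
        list(k = 3L, stride = 2L, pad = 1L, cin = c_prev, cout = out),
        list(k = 3L, stride = 1L, pad = 1L, cin = out, cout = out))
      proj <- list(k = 1L, stride = 2L, pad = 0L, cin = c_prev, cout = out)
      blocks[[length(blocks) + 1L]] <- list(convs = convs, proj = proj)
      c_prev <- out
    }
    # one stride-1 block for extra receptive field
    convs <- list(
      list(k = 3L, stride = 1L, pad = 1L, cin = c_prev, cout = c_prev),
      list(k = 3L, stride = 1L, pad = 1L, cin = c_prev, cout = c_prev))
    blocks[[length(blocks) + 1L]] <- list(convs = convs, proj = NULL)
    feat <- list(k = 1L, stride = 1L, pad = 0L, cin = c_prev, cout = 64L)
    list(stem = stem, blocks = blocks, feat = feat, feat_dim = 64L)
  }
}

init_conv <- function(spec) {
  fan_in <- spec$k * spec$k * spec$cin
  list(w = init_weight(c(spec$k, spec$k, spec$cin, spec$cout), fan_in),
       b = numeric(spec$cout))
}

#' Instantiate a keypoint network
#'
#' Allocates seeded random parameters for the configured backbone and the
#' eight transposed-convolution score-map heads (or warm-starts the backbone
#' from `config$pretrained_weights` when supplied).
#'
#' @param config A [kpnet_config()].
#' @return Object of class `kpnet` (untrained).
#' @export
kpnet <- function(config = kpnet_config()) {
  plan <- kpnet_plan(config)
  params <- with_seed(derive_seed(config$seed, 11L), {
    p <- list(stem = init_conv(plan$stem))
    p$blocks <- lapply(plan$blocks, function(bp) {
      bl <- list(convs = lapply(bp$convs, init_conv))
      if (!is.null(bp$proj)) bl$proj <- init_conv(bp$proj)
      bl
    })
    if (!is.null(plan$feat)) p$feat <- init_conv(plan$feat)
    # heads: one transposed conv, kernel 4 stride 2 pad 1,
    # feat_dim -> n_keypoints; weight layout (kh, kw, Cout, Cin)
    K <- config$n_keypoints
    p$head <- list(
      w = init_weight(c(4L, 4L, K, plan$feat_dim), 4 * 4 * plan$feat_dim),
      b = numeric(K))
    p
  })
  if (!is.null(config$pretrained_weights)) {
    pre <- readRDS(config$pretrained_weights)
    for (nm in intersect(names(pre), c("stem", "blocks", "feat")))
      params[[nm]] <- pre[[nm]]
  }
  structure(list(config = config, plan = plan, params = params,
                 trained = FALSE, loss = numeric(0)),
            class = "kpnet")
}

# ---- forward / backward -------------------------------------------------

block_fw <- function(x, bp, bpar) {
  n <- length(bp$convs)
  as <- vector("list", n)
  zs <- vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    sp <- bp$convs[[i]]
    as[[i]] <- h
    z <- conv2d(h, bpar$convs[[i]]$w, bpar$convs[[i]]$b, sp$stride, sp$pad)
    zs[[i]] <- z
    h <- if (i < n) relu(z) else z
  }
  if (!is.null(bp$proj)) {
    sp <- bp$proj
    sc <- conv2d(x, bpar$proj$w, bpar$proj$b, sp$stride, sp$pad)
  } else sc <- x
  pre <- h + sc
  list(out = relu(pre), cache = list(as = as, zs = zs, pre = pre, x = x))
}

block_bw <- function(dout, bp, bpar, cache) {
  n <- length(bp$convs)
  dpre <- relu_grad(dout, cache$pre)
  grads <- list(convs = vector("list", n))
  if (!is.null(bp$proj)) {
    sp <- bp$proj
    g <- conv2d_grad(cache$x, bpar$proj$w, dpre, sp$stride, sp$pad)
    grads$proj <- list(w = g$dw, b = g$db)
    dx_sc <- g$dx
  } else dx_sc <- dpre
  d <- dpre
  for (i in n:1) {
    sp <- bp$convs[[i]]
    g <- conv2d_grad(cache$as[[i]], bpar$convs[[i]]$w, d, sp$stride, sp$pad)
    grads$convs[[i]] <- list(w = g$dw, b = g$db)
    d <- g$dx
    if (i > 1L) d <- relu_grad(d, cache$zs[[i - 1L]])
  }
  list(dx = d + dx_sc, grads = grads)
}

kpnet_forward_full <- function(model, frame, keep_cache = FALSE) {
  cfg <- model$config
  plan <- model$plan
  par <- model$params
  S <- cfg$input_size
  if (is.matrix(frame)) {
    if (nrow(frame) != S || ncol(frame) != S)
      stop(sprintf("input frame must be %d x %d", S, S))
    x <- array(frame, c(S, S, 1L))
  } else {
    if (!all(dim(frame)[1:2] == c(S, S))) stop("input frame size mismatch")
    x <- frame
  }
  z0 <- conv2d(x, par$stem$w, par$stem$b, plan$stem$stride, plan$stem$pad)
  h <- relu(z0)
  caches <- if (keep_cache) list(x = x, z0 = z0) else NULL
  bcaches <- vector("list", length(plan$blocks))
  for (i in seq_along(plan$blocks)) {
    r <- block_fw(h, plan$blocks[[i]], par$blocks[[i]])
    h <- r$out
    if (keep_cache) bcaches[[i]] <- r$cache
  }
  if (!is.null(plan$feat)) {
    zf <- conv2d(h, par$feat$w, par$feat$b, 1L, 0L)
    hf <- relu(zf)
  } else {
    zf <- NULL; hf <- h
  }
  logits <- deconv2d(hf, par$head$w, par$head$b, 2L, 1L)
  if (keep_cache) {
    caches$bcaches <- bcaches
    caches$h_backbone <- h
    caches$zf <- zf
    caches$hf <- hf
  }
  list(logits = logits, cache = caches)
}

kpnet_backward <- function(model, dlogits, cache) {
  plan <- model$plan
  par <- model$params
  grads <- list()
  g <- deconv2d_grad(cache$hf, par$head$w, dlogits, 2L, 1L)
  grads$head <- list(w = g$dw, b = g$db)
  d <- g$dx
  if (!is.null(plan$feat)) {
    d <- relu_grad(d, cache$zf)
    gf <- conv2d_grad(cache$h_backbone, par$feat$w, d, 1L, 0L)
    grads$feat <- list(w = gf$dw, b = gf$db)
    d <- gf$dx
  }
  nb <- length(plan$blocks)
  grads$blocks <- vector("list", nb)
  for (i in nb:1) {
    r <- block_bw(d, plan$blocks[[i]], par$blocks[[i]],
                  cache$bcaches[[i]])
    grads$blocks[[i]] <- r$grads
    d <- r$dx
  }
  d <- relu_grad(d, cache$z0)
  gs <- conv2d_grad(cache$x, par$stem$w, d, plan$stem$stride, plan$stem$pad)
  grads$stem <- list(w = gs$dw, b = gs$db)
  # reorder to match params element order (stem, blocks, feat, head)
  out <- list(stem = grads$stem, blocks = grads$blocks)
  if (!is.null(plan$feat)) out$feat <- grads$feat
  out$head <- grads$head
  out
}

#' Forward pass: score maps for one frame
#'
#' @param model A `kpnet`.
#' @param frame `input_size x input_size` matrix (or H x W x C array).
#' @return Array `map_size x map_size x n_keypoints` of score maps in
#'   \[0, 1\] (sigmoid of the head logits).
#' @export
kpnet_forward <- function(model, frame) {
  sigmoid(kpnet_forward_full(model, frame)$logits)
}

# ---- targets and readout ------------------------------------------------

#' Binary score-map targets for a set of keypoints
#'
#' A map cell is positive iff its centre, mapped to input coordinates
#' (`x = col * stride + stride / 2`), lies within `positive_radius`
#' (Euclidean) of the keypoint. Invisible keypoints (any NA coordinate, or
#' `visible == FALSE` attribute column) give an all-zero map.
#'
#' @param keypoints `n_keypoints x 2` matrix of `(x, y)` input-pixel
#'   coordinates.
#' @param config A [kpnet_config()].
#' @return Array `map_size x map_size x n_keypoints` of 0/1 targets.
#' @export
make_target <- function(keypoints, config) {
  m <- config$map_size
  ms <- config$map_stride
  K <- config$n_keypoints
  if (nrow(keypoints) != K) stop("keypoint count mismatch")
  centers <- (0:(m - 1)) * ms + ms / 2
  tgt <- array(0, c(m, m, K))
  for (k in seq_len(K)) {
    x <- keypoints[k, 1]; y <- keypoints[k, 2]
    if (is.na(x) || is.na(y)) next
    dx2 <- (centers - x)^2   # over columns
    dy2 <- (centers - y)^2   # over rows
    tgt[, , k] <- outer(dy2, dx2, "+") <= config$positive_radius^2
  }
  tgt
}

#' Read keypoint coordinates from score maps
#'
#' Arg-max readout maps the peak cell back to input coordinates by the
#' cell-centre convention `x = col * stride + stride / 2`; ties are broken
#' toward the smallest `(y, x)`. The soft variant takes the
#' softmax-weighted (inverse temperature `beta`) mean of the cell centres,
#' which is differentiable and sub-cell accurate.
#'
#' @param maps `map_size x map_size x K` score-map array.
#' @param map_stride Input pixels per map cell.
#' @param method `"argmax"` or `"soft"`.
#' @param beta Soft-argmax inverse temperature.
#' @return `K x 2` matrix of `(x, y)` input coordinates (rownames
#'   [keypoint_names()] when K = 8).
#' @export
readout <- function(maps, map_stride, method = c("argmax", "soft"), beta = 25) {
  method <- match.arg(method)
  m <- dim(maps)[1]
  K <- dim(maps)[3]
  centers <- (0:(m - 1)) * map_stride + map_stride / 2
  out <- matrix(NA_real_, K, 2, dimnames = list(NULL, c("x", "y")))
  for (k in seq_len(K)) {
    mp <- maps[, , k]
    if (method == "argmax") {
      mx <- max(mp)
      hits <- which(mp == mx, arr.ind = TRUE)  # (row, col), 1-based
      # smallest (y, x): order by row then column
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      i <- hits[1, 1] - 1L; j <- hits[1, 2] - 1L
      out[k, ] <- c(j * map_stride + map_stride / 2,
                    i * map_stride + map_stride / 2)
    } else {
      w <- exp(beta * (mp - max(mp)))
      w <- w / sum(w)
      out[k, ] <- c(sum(colSums(w) * centers), sum(rowSums(w) * centers))
    }
  }
  if (K == 8L) rownames(out) <- keypoint_names()
  out
}

# ---- training -----------------------------------------------------------

#' Train the keypoint network
#'
#' Seeded SGD with momentum on per-pixel weighted binary cross-entropy
#' between the head logits and [make_target()] maps.
#'
#' @param frames List of `input_size x input_size` matrices.
#' @param keypoints List of `n_keypoints x 2` coordinate matrices (same
#'   length as `frames`).
#' @param config A [kpnet_config()].
#' @param model Optional existing `kpnet` to continue training.
#' @return A trained `kpnet` with a per-iteration `loss` curve.
#' @export
train_kpnet <- function(frames, keypoints, config = kpnet_config(),
                        model = NULL) {
  if (length(frames) == 0L) stop("empty training set")
  if (length(frames) != length(keypoints))
    stop("frames and keypoints must have equal length")
  if (is.null(model)) model <- kpnet(config) else config <- model$config
  targets <- lapply(keypoints, make_target, config = config)
  vel <- zero_like(model$params)
  loss_curve <- numeric(config$iters)
  n <- length(frames)
  for (it in seq_len(config$iters)) {
    batch_idx <- with_seed(derive_seed(config$seed, 21L, it),
                           sample.int(n, min(config$batch, n)))
    grads <- NULL
    loss <- 0
    for (b in batch_idx) {
      fw <- kpnet_forward_full(model, frames[[b]], keep_cache = TRUE)
      l <- bce_with_logits(fw$logits, targets[[b]], config$pos_weight)
      loss <- loss + l$loss
      g <- kpnet_backward(model, l$dlogits, fw$cache)
      grads <- if (is.null(grads)) g else accum_grads(grads, g)
    }
    grads <- scale_grads(grads, 1 / length(batch_idx))
    stp <- sgd_step(model$params, grads, vel, config$lr, config$momentum)
    model$params <- stp$params
    vel <- stp$vel
    loss_curve[it] <- loss / length(batch_idx)
  }
  model$loss <- c(model$loss, loss_curve)
  model$trained <- TRUE
  model
}

#' Predict keypoints for frames
#'
#' @param object A `kpnet`.
#' @param frames A single frame matrix or a list of frames.
#' @param type `"keypoints"` (default) or `"maps"` (raw score maps).
#' @param ... Unused.
#' @return A keypoint matrix (or score-map array), or a list of them.
#' @export
predict.kpnet <- function(object, frames, type = c("keypoints", "maps"), ...) {
  type <- match.arg(type)
  one <- function(fr) {
    maps <- kpnet_forward(object, fr)
    if (type == "maps") maps
    else readout(maps, object$config$map_stride, object$config$readout,
                 object$config$soft_beta)
  }
  if (is.matrix(frames)) one(frames) else lapply(frames, one)
}

#' Per-keypoint localisation error
#'
#' Euclidean pixel distance per named keypoint plus the RMSE over points
#' (the summary used for keypoint-accuracy curves).
#'
#' @param pred,truth `K x 2` coordinate matrices with matching rownames
#'   (or lists of them, aggregated jointly).
#' @return List with `distances` (named vector, or matrix for lists),
#'   `mean` and `rmse`.
#' @export
keypoint_error <- function(pred, truth) {
  pair_err <- function(p, y) {
    if (!is.null(rownames(p)) && !is.null(rownames(y))) {
      if (!setequal(rownames(p), rownames(y)))
        stop("keypoint names do not match")
      y <- y[rownames(p), , drop = FALSE]
    } else if (nrow(p) != nrow(y)) stop("keypoint count mismatch")
    d <- sqrt(rowSums((p - y)^2))
    names(d) <- rownames(p)
    d
  }
  if (is.list(pred)) {
    dmat <- do.call(rbind, Map(pair_err, pred, truth))
    list(distances = dmat, mean = mean(dmat), rmse = sqrt(mean(dmat^2)))
  } else {
    d <- pair_err(pred, truth)
    list(distances = d, mean = mean(d), rmse = sqrt(mean(d^2)))
  }
}

# ---- shapes -------------------------------------------------------------

#' Per-stage output shapes of the keypoint network
#'
#' Closed-form shape ladder for a given configuration: stem, the residual
#' stages, the deconvolutional score-map heads, the readout coordinates and
#' the flattened keypoint vector. With the default full-scale configuration
#' (input 512, ResNet-50 backbone) the ladder is 256x256x64, 128x128x256,
#' 64x64x512, 32x32x1024, 32x32x2048, score maps 64x64x8, readout 2x8 and
#' keypoint vector 16.
#'
#' @param config A [kpnet_config()].
#' @return data.frame with columns `layer`, `side`, `channels`.
#' @export
kpnet_shapes <- function(config = kpnet_config()) {
  plan <- kpnet_plan(config)
  S <- config$input_size
  rows <- list()
  side <- S %/% plan$stem$stride
  rows[[1]] <- data.frame(layer = "stem_conv", side = side,
                          channels = plan$stem$cout)
  for (i in seq_along(plan$blocks)) {
    bp <- plan$blocks[[i]]
    s <- prod(vapply(bp$convs, function(cv) cv$stride, numeric(1)))
    side <- side %/% s
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("block_%d", i), side = side,
      channels = bp$convs[[length(bp$convs)]]$cout)
  }
  if (!is.null(plan$feat))
    rows[[length(rows) + 1L]] <- data.frame(layer = "feat_conv", side = side,
                                            channels = plan$feat$cout)
  rows[[length(rows) + 1L]] <- data.frame(layer = "score_maps",
                                          side = side * 2L,
                                          channels = config$n_keypoints)
  rows[[length(rows) + 1L]] <- data.frame(layer = "readout", side = 2L,
                                          channels = config$n_keypoints)
  rows[[length(rows) + 1L]] <- data.frame(layer = "keypoint_vector",
                                          side = 2L * config$n_keypoints,
                                          channels = 1L)
  do.call(rbind, rows)
}

#' @export
print.kpnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<kpnet> %s backbone, input %d, %d score maps of %d x %d (stride %d)%s\n",
              cfg$backbone, cfg$input_size, cfg$n_keypoints, cfg$map_size,
              cfg$map_size, cfg$map_stride,
              if (x$trained) sprintf(", trained (%d iterations, final loss %.4g)",
                                     length(x$loss), tail(x$loss, 1)) else
                ", untrained"))
  invisible(x)
}
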