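# Thin R wrappers over the C++ layer kernels, plus the activations and the
# SGD machinery shared by both network channels.
#
# Tensor layouts (column-major R arrays):
#   2-D feature maps: (H, W, C); 3-D feature maps: (T, H, W, C)
#   2-D conv weights: (kh, kw, Cin, Cout); transposed-conv weights:
#   (kh, kw, Cout, Cin); 3-D conv weights: (kt, kh, kw, Cin, Cout)

conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  cpp_conv2d_fw(x, w, b, as.integer(stride), as.integer(pad))
}

conv2d_grad <- function(x, w, dout, stride = 1L, pad = 0L) {
  list(
    dx = cpp_conv2d_bw_input(dout, w, dim(x)[1], dim(x)[2],
                             as.integer(stride), as.integer(pad)),
    dw = cpp_conv2d_bw_filter(x, dout, dim(w)[1], dim(w)[2],
                              as.integer(stride), as.integer(pad)),
    db = apply(dout, 3, sum)
  )
}

# Transposed convolution: output side (n - 1) * stride + k - 2 * pad.
# Forward is the input-gradient of the matching convolution.
deconv2d <- function(x, w, b, stride = 2L, pad = 1L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  Ho <- (dim(x)[1] - 1L) * stride + kh - 2L * pad
  Wo <- (dim(x)[2] - 1L) * stride + kw - 2L * pad
  y <- cpp_conv2d_bw_input(x, w, Ho, Wo, as.integer(stride), as.integer(pad))
  sweep(y, 3, b, "+")
}

deconv2d_grad <- function(x, w, dout, stride = 2L, pad = 1L) {
  zero_b <- numeric(dim(w)[4])
  list(
    dx = cpp_conv2d_fw(dout, w, zero_b, as.integer(stride), as.integer(pad)),
    dw = cpp_conv2d_bw_filter(dout, x, dim(w)[1], dim(w)[2],
                              as.integer(stride), as.integer(pad)),
    db = apply(dout, 3, sum)
  )
}

conv3d <- function(x, w, b, stride = 1L, pad_t = 0L, pad = 0L) {
  cpp_conv3d_fw(x, w, b, as.integer(stride), as.integer(pad_t),
                as.integer(pad))
}

conv3d_grad <- function(x, w, dout, stride = 1L, pad_t = 0L, pad = 0L) {
  list(
    dx = cpp_conv3d_bw_input(dout, w, dim(x)[1], dim(x)[2], dim(x)[3],
                             as.integer(stride), as.integer(pad_t),
                             as.integer(pad)),
    dw = cpp_conv3d_bw_filter(x, dout, dim(w)[1], dim(w)[2], dim(w)[3],
                              as.integer(stride), as.integer(pad_t),
                              as.integer(pad)),
    db = apply(dout, 4, sum)
  )
}

maxpool3d <- function(x) cpp_maxpool3d_fw(x)

maxpool3d_grad <- function(dout, cache_argmax, xdim) {
  cpp_maxpool3d_bw(dout, cache_argmax, as.integer(xdim))
}

relu <- function(x) {
  y <- pmax(x, 0)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

relu_grad <- function(dout, x) {
  g <- dout * (x > 0)
  if (!is.null(dim(dout))) dim(g) <- dim(dout)
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable softmax over a vector (or the rows of a matrix).
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

# Weighted per-pixel binary cross-entropy on logits.
# Positive targets weighted by pos_weight to offset their scarcity in
# score-map targets. Returns loss and gradient w.r.t. logits.
bce_with_logits <- function(logits, targets, pos_weight = 1) {
  s <- sigmoid(logits)
  eps <- 1e-12
  n <- length(logits)
  loss <- -sum(pos_weight * targets * log(s + eps) +
                 (1 - targets) * log(1 - s + eps)) / n
  dlogits <- (s * ((pos_weight - 1) * targets + 1) - pos_weight * targets) / n
  if (!is.null(dim(logits))) dim(dlogits) <- dim(logits)
  list(loss = loss, dlogits = dlogits)
}

# Multinomial cross-entropy on logits for one sample.
# label is a 0-based class index.
ce_with_logits <- function(logits, label) {
  p <- softmax(logits)
  eps <- 1e-12
  loss <- -log(p[label + 1L] + eps)
  d <- p
  d[label + 1L] <- d[label + 1L] - 1
  list(loss = loss, dlogits = d, prob = p)
}

# Seeded fan-in uniform initialisation (limit sqrt(6 / fan_in)); draws come
# from the current RNG stream, which callers seed via with_seed().
init_weight <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# Global L2 norm of a nested gradient list, and norm clipping.
grad_global_norm <- function(g) {
  total <- 0
  walk <- function(v) {
    if (is.list(v)) lapply(v, walk) else total <<- total + sum(v * v)
    invisible(NULL)
  }
  walk(g)
  sqrt(total)
}

clip_grads <- function(g, max_norm) {
  nrm <- grad_global_norm(g)
  if (is.finite(max_norm) && nrm > max_norm) scale_grads(g, max_norm / nrm)
  else g
}

# ---- SGD with momentum over nested parameter lists ---------------------

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else { z <- p; z[] <- 0; z }
}

accum_grads <- function(a, b) {
  if (is.list(a)) mapply(accum_grads, a, b, SIMPLIFY = FALSE)
  else a + b
}

scale_grads <- function(a, s) {
  if (is.list(a)) lapply(a, scale_grads, s = s)
  else a * s
}

sgd_step <- function(params, grads, vel, lr, momentum = 0) {
  if (is.list(params)) {
    out <- mapply(sgd_step, params, grads, vel,
                  MoreArgs = list(lr = lr, momentum = momentum),
                  SIMPLIFY = FALSE)
    list(params = lapply(out, `[[`, "params"),
         vel = lapply(out, `[[`, "vel"))
  } else {
    v <- momentum * vel - lr * grads
    list(params = params + v, vel = v)
  }
}
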