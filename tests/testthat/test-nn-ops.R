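# Layer kernels against naive R oracles and numeric gradients.

naive_conv2d <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; F <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + 1:H, pad + 1:W, ] <- x
  y <- array(0, c(Ho, Wo, F))
  for (f in 1:F) for (i in 1:Ho) for (j in 1:Wo)
    y[i, j, f] <- sum(xp[(i - 1) * stride + 1:kh,
                         (j - 1) * stride + 1:kw, , drop = FALSE] *
                        w[, , , f]) + b[f]
  y
}

numeric_grad <- function(f, arr, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    a1 <- arr; a1[i] <- a1[i] + eps
    a2 <- arr; a2[i] <- a2[i] - eps
    (f(a1) - f(a2)) / (2 * eps)
  }, numeric(1))
}

test_that("conv2d matches a naive convolution for all stride/pad combos", {
  set.seed(42)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- rnorm(4)
  for (st in 1:2) for (pd in 0:1) {
    expect_equal(pf$conv2d(x, w, b, st, pd), naive_conv2d(x, w, b, st, pd),
                 tolerance = 1e-12)
  }
})

test_that("conv2d gradients agree with finite differences", {
  set.seed(7)
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  loss <- function(x, w, b) sum(sin(pf$conv2d(x, w, b, 2, 1)))
  dout <- cos(pf$conv2d(x, w, b, 2, 1))
  g <- pf$conv2d_grad(x, w, dout, 2, 1)
  ix <- sample(length(x), 10)
  expect_equal(numeric_grad(function(a) loss(a, w, b), x, ix), g$dx[ix],
               tolerance = 1e-6)
  iw <- sample(length(w), 10)
  expect_equal(numeric_grad(function(a) loss(x, a, b), w, iw), g$dw[iw],
               tolerance = 1e-6)
  expect_equal(g$db, apply(dout, 3, sum))
})

test_that("transposed convolution upsamples 2x and its gradients check out", {
  set.seed(11)
  x <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  w <- array(rnorm(4 * 4 * 3 * 5), c(4, 4, 3, 5))  # (kh, kw, Cout, Cin)
  b <- rnorm(3)
  y <- pf$deconv2d(x, w, b)
  expect_equal(dim(y), c(8L, 8L, 3L))
  loss <- function(x, w, b) sum(sin(pf$deconv2d(x, w, b)))
  g <- pf$deconv2d_grad(x, w, cos(y))
  ix <- sample(length(x), 10)
  expect_equal(numeric_grad(function(a) loss(a, w, b), x, ix), g$dx[ix],
               tolerance = 1e-6)
  iw <- sample(length(w), 10)
  expect_equal(numeric_grad(function(a) loss(x, a, b), w, iw), g$dw[iw],
               tolerance = 1e-6)
  expect_equal(g$db, apply(cos(y), 3, sum))
})

test_that("conv3d with anisotropic padding matches finite differences", {
  set.seed(13)
  x <- array(rnorm(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  w <- array(rnorm(3 * 5 * 5 * 2 * 2), c(3, 5, 5, 2, 2))
  b <- rnorm(2)
  y <- pf$conv3d(x, w, b, 1, 1, 2)
  expect_equal(dim(y), c(4L, 6L, 6L, 2L))  # same-padded
  loss <- function(x, w) sum(sin(pf$conv3d(x, w, b, 1, 1, 2)))
  g <- pf$conv3d_grad(x, w, cos(y), 1, 1, 2)
  ix <- sample(length(x), 10)
  expect_equal(numeric_grad(function(a) loss(a, w), x, ix), g$dx[ix],
               tolerance = 1e-6)
  iw <- sample(length(w), 10)
  expect_equal(numeric_grad(function(a) loss(x, a), w, iw), g$dw[iw],
               tolerance = 1e-6)
})

test_that("max pooling halves every dimension and routes gradients to argmax", {
  set.seed(17)
  x <- array(rnorm(4 * 6 * 8 * 3), c(4, 6, 8, 3))
  p <- pf$maxpool3d(x)
  expect_equal(dim(p$out), c(2L, 3L, 4L, 3L))
  # every pooled value is the max of its 2x2x2 window
  expect_true(all(p$out == x[p$argmax]))
  g <- pf$maxpool3d_grad(cos(p$out), p$argmax, dim(x))
  ix <- sample(length(x), 15)
  num <- numeric_grad(function(a) sum(sin(pf$maxpool3d(a)$out)), x, ix,
                      eps = 1e-5)
  expect_equal(num, g[ix], tolerance = 1e-5)
})

test_that("softmax outputs are simplex points over many random inputs", {
  set.seed(19)
  for (i in 1:200) {
    p <- pf$softmax(rnorm(3, sd = 10))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  expect_equal(pf$softmax(c(0, 0, 0)), rep(1 / 3, 3))
})

test_that("weighted binary cross-entropy gradient matches finite differences", {
  set.seed(23)
  z <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  y <- array(rbinom(50, 1, 0.2), c(5, 5, 2))
  l <- pf$bce_with_logits(z, y, pos_weight = 20)
  ix <- sample(length(z), 12)
  num <- numeric_grad(function(a) pf$bce_with_logits(a, y, 20)$loss, z, ix)
  expect_equal(num, l$dlogits[ix], tolerance = 1e-6)
})
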