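# Delta-F-over-F: trace extraction, the four-step computation, and its
# invariances.

test_that("trace extraction reduces to means and the background minimum", {
  masks <- list(roi = matrix(FALSE, 4, 4), ring = matrix(FALSE, 4, 4),
                background = matrix(FALSE, 4, 4))
  masks$roi[1, 1:2] <- TRUE
  masks$ring[2, 1:2] <- TRUE
  masks$background[4, ] <- TRUE
  # constant stack
  stc <- array(7, c(3, 4, 4))
  tr <- extract_traces(stc, masks)
  expect_equal(tr$F_raw, rep(7, 3))
  expect_equal(tr$F_ring, rep(7, 3))
  expect_equal(tr$F_b, 7)
  # roi pixels {4, 6} -> mean 5; background over frames {3, 2, 7} -> min 2
  st <- array(0, c(3, 4, 4))
  st[1, 1, 1] <- 4; st[1, 1, 2] <- 6
  st[1, 4, ] <- 3; st[2, 4, ] <- 2; st[3, 4, ] <- 7
  tr2 <- extract_traces(st, masks)
  expect_equal(tr2$F_raw[1], 5)
  expect_equal(tr2$F_b, 2)
  # malformed masks
  expect_error(extract_traces(stc, list(roi = masks$roi, ring = masks$ring,
                                        background = matrix(FALSE, 4, 4))),
               "empty")
  expect_error(extract_traces(stc, list(roi = matrix(TRUE, 2, 2),
                                        ring = masks$ring,
                                        background = masks$background)),
               "shape")
})

test_that("the four-step computation reproduces hand arithmetic", {
  # F_ROI = 10 - 2 = 8; F_con = 6 - 2 = 4; F_sig = 8 - 0.9 * 4 = 4.4
  rec <- compute_dff(fluorescence_record(10, 6, 2, alpha = 0.9))
  expect_equal(rec$F_ROI, 8)
  expect_equal(rec$F_con, 4)
  expect_equal(rec$F_sig, 4.4)
  expect_equal(rec$F0, 8)
  expect_equal(rec$dff, 4.4 / 8)
  # null signal: F_raw and F_ring at background level
  r0 <- compute_dff(fluorescence_record(c(2, 2), c(2, 2), 2))
  expect_equal(r0$F_sig, c(0, 0))
  expect_equal(r0$dff, c(0, 0))
  # alpha = 0: ring trace is ignored entirely
  ra <- compute_dff(fluorescence_record(c(10, 12), c(6, 99), 2, alpha = 0))
  expect_equal(ra$dff, (c(10, 12) - 2) / mean(c(10, 12) - 2))
  # F0 <= 0 with a real signal is an error naming the estimate
  expect_error(compute_dff(fluorescence_record(c(1, 3), c(5, 5), 2)),
               "F0")
  expect_error(fluorescence_record(1, 1, 0, alpha = 1.2), "alpha")
})

test_that("dFF is scale invariant and strictly increasing in F_raw", {
  set.seed(31)
  F_raw <- 50 + runif(20, 0, 10)
  F_ring <- 45 + runif(20, 0, 5)
  F_b <- 40
  base <- compute_dff(fluorescence_record(F_raw, F_ring, F_b))
  for (c_ in c(0.5, 3, 100)) {
    scaled <- compute_dff(fluorescence_record(c_ * F_raw, c_ * F_ring,
                                              c_ * F_b))
    expect_equal(scaled$dff, base$dff, tolerance = 1e-12)
  }
  # monotonicity: raising one F_raw sample raises its dFF
  for (i in c(1, 7, 20)) {
    up <- F_raw; up[i] <- up[i] + 1
    bumped <- compute_dff(fluorescence_record(up, F_ring, F_b),
                          baseline_window = seq_len(20)[-i])
    ref <- compute_dff(fluorescence_record(F_raw, F_ring, F_b),
                       baseline_window = seq_len(20)[-i])
    expect_gt(bumped$dff[i], ref$dff[i])
  }
})

test_that("trace-level dFF equals a per-pixel brute-force recomputation", {
  sig <- c(rep(0, 6), 3, 5, 3, rep(0, 6))
  st <- generate_fluorescence_stack(80, sig, ring_contamination = 1.5,
                                    noise_sigma = 0.5, seed = 12, side = 24)
  rec <- compute_dff(st$stack, masks = st$masks)
  # independent brute force: loop pixels in R, then apply the four steps
  Tn <- dim(st$stack)[1]
  raw <- ring <- numeric(Tn)
  bg <- Inf
  for (t in seq_len(Tn)) {
    fr <- st$stack[t, , ]
    s_roi <- 0; n_roi <- 0; s_ring <- 0; n_ring <- 0
    for (i in seq_len(nrow(fr))) for (j in seq_len(ncol(fr))) {
      if (st$masks$roi[i, j]) { s_roi <- s_roi + fr[i, j]; n_roi <- n_roi + 1 }
      if (st$masks$ring[i, j]) { s_ring <- s_ring + fr[i, j]; n_ring <- n_ring + 1 }
      if (st$masks$background[i, j]) bg <- min(bg, fr[i, j])
    }
    raw[t] <- s_roi / n_roi
    ring[t] <- s_ring / n_ring
  }
  f_roi <- raw - bg
  f_sig <- f_roi - 0.9 * (ring - bg)
  expect_equal(rec$dff, f_sig / mean(f_roi), tolerance = 1e-9)
})

test_that("records round-trip through the CSV writers", {
  rec <- compute_dff(fluorescence_record(c(10, 11, 12), c(6, 6, 7), 2))
  path <- tempfile(fileext = ".csv")
  write_dff_csv(rec, path)
  df <- read.csv(path)
  expect_equal(df$dff, rec$dff)
  rec2 <- read_traces_csv(path, F_b = 2)
  expect_equal(compute_dff(rec2)$dff, rec$dff)
  unlink(path)
})
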