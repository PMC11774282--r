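# Infraorbital-nerve activity: delta-F-over-F from fluorescence stacks.
#
# The pipeline is the standard ring-subtraction one:
#   F_ROI = F_raw - F_b          (background-subtracted ROI trace)
#   F_con = F_ring - F_b         (out-of-focus contamination estimate)
#   F_sig = F_ROI - alpha * F_con
#   dFF   = F_sig / F0,  F0 = mean of F_ROI over a baseline window
# where F_raw is the per-frame ROI mean, F_ring the per-frame mean over an
# annulus around the ROI, and F_b the minimum of the stack restricted to a
# background region.

#' Extract ROI / ring / background traces from an image stack
#'
#' @param stack Numeric array `T x H x W` (frames first).
#' @param masks List with logical `H x W` matrices `roi`, `ring`,
#'   `background`; pairwise disjoint, each nonempty.
#' @return List with `F_raw` and `F_ring` (length-T traces) and scalar
#'   `F_b` (minimum over all frames restricted to the background mask).
#' @export
extract_traces <- function(stack, masks) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[1] < 1L)
    stop("stack must be a nonempty T x H x W array")
  for (nm in c("roi", "ring", "background")) {
    m <- masks[[nm]]
    if (is.null(m) || !is.logical(m)) stop(sprintf("missing logical mask '%s'", nm))
    if (!all(dim(m) == d[2:3])) stop(sprintf("mask '%s' does not match frame shape", nm))
    if (!any(m)) stop(sprintf("mask '%s' is empty", nm))
  }
  Tn <- d[1]
  F_raw <- numeric(Tn)
  F_ring <- numeric(Tn)
  bg_min <- Inf
  for (t in seq_len(Tn)) {
    fr <- stack[t, , ]
    F_raw[t] <- mean(fr[masks$roi])
    F_ring[t] <- mean(fr[masks$ring])
    bg_min <- min(bg_min, min(fr[masks$background]))
  }
  list(F_raw = F_raw, F_ring = F_ring, F_b = bg_min)
}

#' Build a fluorescence record
#'
#' @param F_raw Per-frame mean ROI intensity (>= 0).
#' @param F_ring Per-frame mean ring intensity (>= 0), same length.
#' @param F_b Scalar background baseline (>= 0).
#' @param alpha Contamination coefficient in \[0, 1\] (default 0.9).
#' @return Object of class `fluorescence_record`.
#' @export
fluorescence_record <- function(F_raw, F_ring, F_b, alpha = 0.9) {
  if (length(F_raw) != length(F_ring))
    stop("F_raw and F_ring must have equal length")
  if (any(F_raw < 0) || any(F_ring < 0) || F_b < 0)
    stop("raw intensities must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(F_raw = as.numeric(F_raw), F_ring = as.numeric(F_ring),
                 F_b = as.numeric(F_b), alpha = alpha),
            class = "fluorescence_record")
}

#' Compute the delta-F-over-F trace
#'
#' Derives `F_ROI = F_raw - F_b`, `F_con = F_ring - F_b`,
#' `F_sig = F_ROI - alpha * F_con` and `dff = F_sig / F0`, with `F0`
#' estimated as the mean of `F_ROI` over `baseline_window` (default: the
#' whole trace). If the baseline estimate is non-positive the computation
#' stops with an error naming it, except in the fully degenerate case where
#' the signal trace is identically zero, for which `dff` is the zero trace
#' (a flat record carries no activity by definition).
#'
#' @param record A [fluorescence_record()], or a list/stack input accepted
#'   by [extract_traces()] together with `masks`.
#' @param baseline_window Integer indices of frames used for `F0`
#'   (default all).
#' @param masks Optional masks when `record` is a raw stack.
#' @return The input record augmented with `F_ROI`, `F_con`, `F_sig`, `F0`
#'   and `dff`, class `fluorescence_record`.
#' @export
compute_dff <- function(record, baseline_window = NULL, masks = NULL) {
  if (is.array(record) && length(dim(record)) == 3L) {
    if (is.null(masks)) stop("masks are required when passing a raw stack")
    tr <- extract_traces(record, masks)
    record <- fluorescence_record(tr$F_raw, tr$F_ring, tr$F_b)
  }
  stopifnot(inherits(record, "fluorescence_record"))
  n <- length(record$F_raw)
  if (is.null(baseline_window)) baseline_window <- seq_len(n)
  if (any(baseline_window < 1L) || any(baseline_window > n))
    stop("baseline_window indices out of range")
  F_ROI <- record$F_raw - record$F_b
  F_con <- record$F_ring - record$F_b
  F_sig <- F_ROI - record$alpha * F_con
  F0 <- mean(F_ROI[baseline_window])
  if (F0 <= 0) {
    if (all(abs(F_sig) < 1e-12)) {
      dff <- numeric(n)
    } else {
      stop(sprintf("baseline estimate F0 = %g is not positive; choose a baseline window with fluorescence above background", F0))
    }
  } else {
    dff <- F_sig / F0
  }
  record$F_ROI <- F_ROI
  record$F_con <- F_con
  record$F_sig <- F_sig
  record$F0 <- F0
  record$dff <- dff
  record
}

#' @export
print.fluorescence_record <- function(x, ...) {
  cat(sprintf("<fluorescence_record> %d frames, alpha = %g, F_b = %g\n",
              length(x$F_raw), x$alpha, x$F_b))
  if (!is.null(x$dff))
    cat(sprintf("  F0 = %g; dFF range [%g, %g]\n", x$F0,
                min(x$dff), max(x$dff)))
  invisible(x)
}

#' @export
plot.fluorescence_record <- function(x, ...) {
  if (is.null(x$dff)) x <- compute_dff(x)
  graphics::plot(seq_along(x$dff), x$dff, type = "l",
                 xlab = "frame", ylab = expression(Delta * F / F), ...)
  invisible(x)
}

#' Write derived fluorescence traces to CSV
#'
#' Columns: `t`, `F_raw`, `F_ring`, `F_ROI`, `F_con`, `F_sig`, `dff`.
#'
#' @param record A computed [fluorescence_record()].
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_dff_csv <- function(record, path) {
  if (is.null(record$dff)) record <- compute_dff(record)
  df <- data.frame(t = seq_along(record$F_raw) - 1L,
                   F_raw = record$F_raw, F_ring = record$F_ring,
                   F_ROI = record$F_ROI, F_con = record$F_con,
                   F_sig = record$F_sig, dff = record$dff)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read traces from CSV (columns t, F_raw, F_ring) into a record
#'
#' @param path CSV path.
#' @param F_b Background baseline scalar.
#' @param alpha Contamination coefficient.
#' @return A [fluorescence_record()].
#' @export
read_traces_csv <- function(path, F_b, alpha = 0.9) {
  df <- read.csv(path)
  fluorescence_record(df$F_raw, df$F_ring, F_b, alpha)
}
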