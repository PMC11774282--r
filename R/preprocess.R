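# Image pipeline: face crop + resize, blur rejection, class balancing,
# clip assembly and train/test splitting.

#' Crop a region and resize it to a square
#'
#' The crop box is `(x, y, w, h)` in 0-based source pixel coordinates; the
#' crop is resized (bilinear, no padding) to `out_size x out_size`.
#'
#' @param image Numeric matrix (rows = y).
#' @param crop_box Numeric vector `c(x, y, w, h)`; default: the full frame.
#' @param out_size Output side in pixels (default 512).
#' @return `out_size x out_size` numeric matrix.
#' @export
crop_and_resize <- function(image, crop_box = NULL, out_size = 512L) {
  H <- nrow(image); W <- ncol(image)
  if (is.null(crop_box)) crop_box <- c(0, 0, W, H)
  x <- crop_box[1]; y <- crop_box[2]; w <- crop_box[3]; h <- crop_box[4]
  if (w < 1 || h < 1) stop("crop box must have positive width and height")
  if (x < 0 || y < 0 || x + w > W || y + h > H)
    stop("crop box out of source bounds")
  sub <- image[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
  if (nrow(sub) == out_size && ncol(sub) == out_size) return(sub)
  out <- EBImage::resize(EBImage::Image(sub), w = out_size, h = out_size)
  matrix(EBImage::imageData(out), out_size, out_size)
}

#' Transform keypoints consistently with [crop_and_resize()]
#'
#' @param keypoints `n x 2` matrix of `(x, y)` source coordinates.
#' @param crop_box The crop box applied to the image.
#' @param out_size Output side.
#' @param src_dim `c(H, W)` of the source image (used when `crop_box` is
#'   NULL).
#' @return Transformed `n x 2` matrix.
#' @export
transform_keypoints <- function(keypoints, crop_box = NULL, out_size = 512L,
                                src_dim = NULL) {
  if (is.null(crop_box)) {
    if (is.null(src_dim)) stop("need crop_box or src_dim")
    crop_box <- c(0, 0, src_dim[2], src_dim[1])
  }
  out <- keypoints
  out[, 1] <- (keypoints[, 1] - crop_box[1]) * out_size / crop_box[3]
  out[, 2] <- (keypoints[, 2] - crop_box[2]) * out_size / crop_box[4]
  out
}

#' Sharpness score of an image
#'
#' Variance of the 3x3 Laplacian response over the image interior; zero for
#' a constant image, higher for sharper images. Used to reject
#' motion-blurred frames.
#'
#' @param image Numeric matrix.
#' @return Non-negative scalar.
#' @export
blur_score <- function(image) {
  H <- nrow(image); W <- ncol(image)
  if (is.null(H) || H < 3 || W < 3) stop("image must be at least 3 x 3")
  core <- image[2:(H - 1), 2:(W - 1)]
  lap <- image[1:(H - 2), 2:(W - 1)] + image[3:H, 2:(W - 1)] +
    image[2:(H - 1), 1:(W - 2)] + image[2:(H - 1), 3:W] - 4 * core
  v <- var(as.vector(lap))
  if (is.na(v)) 0 else v
}

#' Balance classes by seeded subsampling
#'
#' @param records data.frame with a `grade` column (and optionally a
#'   logical `kept` column; only kept records are eligible).
#' @param n_per_class Records to keep per class.
#' @param seed Integer seed.
#' @return Subset of `records` with exactly `n_per_class` rows per class,
#'   sampled without replacement.
#' @export
balance_classes <- function(records, n_per_class, seed = 1L) {
  eligible <- if ("kept" %in% names(records)) records[records$kept, ] else records
  picks <- with_seed(seed, {
    unlist(lapply(sort(unique(records$grade)), function(g) {
      rows <- which(eligible$grade == g)
      if (length(rows) < n_per_class)
        stop(sprintf("class %s has only %d kept records (< %d requested)",
                     g, length(rows), n_per_class), call. = FALSE)
      sample(rows, n_per_class)
    }))
  })
  eligible[sort(picks), , drop = FALSE]
}

#' Assemble sliding-window clip indices from a frame table
#'
#' Frames must be in source (time) order. Windows of length `T` at the given
#' stride are emitted only when every frame in the window is kept, so no
#' clip spans a rejected (blurry) frame.
#'
#' @param records data.frame of frames in time order, with an optional
#'   logical `kept` column (default: all kept).
#' @param T Clip length in frames (default 16).
#' @param stride Window stride (default `T`, i.e. non-overlapping).
#' @return List of integer row-index vectors, one per clip; empty (with a
#'   warning) when no window of `T` contiguous kept frames exists.
#' @export
make_clips <- function(records, T = 16L, stride = T) {
  n <- nrow(records)
  kept <- if ("kept" %in% names(records)) records$kept else rep(TRUE, n)
  clips <- list()
  start <- 1L
  while (start + T - 1L <= n) {
    window <- start:(start + T - 1L)
    if (all(kept[window])) {
      clips[[length(clips) + 1L]] <- window
      start <- start + stride
    } else {
      # jump past the last rejected frame in the window
      start <- max(window[!kept[window]]) + 1L
    }
  }
  if (length(clips) == 0L)
    warning(sprintf("no window of %d contiguous kept frames", T))
  clips
}

#' Seeded train/test split
#'
#' @param items Vector or list to split.
#' @param fraction Training fraction (default 0.8); the split point is
#'   `floor(fraction * n)` after a seeded shuffle.
#' @param seed Integer seed.
#' @param groups Optional grouping vector (e.g. animal id): when given, the
#'   split is performed over groups so no group spans both sets.
#' @return List with `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(items, fraction = 0.8, seed = 1L, groups = NULL) {
  n <- if (is.list(items)) length(items) else length(items)
  if (n < 2L) stop("need at least 2 items to split")
  idx <- if (is.null(groups)) {
    perm <- with_seed(seed, sample.int(n))
    k <- floor(fraction * n)
    list(train = perm[seq_len(k)], test = perm[setdiff(seq_len(n), seq_len(k))])
  } else {
    gs <- unique(groups)
    perm <- with_seed(seed, sample(gs))
    k <- floor(fraction * length(gs))
    tr_g <- perm[seq_len(k)]
    list(train = which(groups %in% tr_g), test = which(!groups %in% tr_g))
  }
  pick <- function(v, i) if (is.list(v)) v[i] else v[i]
  list(train = pick(items, idx$train), test = pick(items, idx$test),
       train_idx = idx$train, test_idx = idx$test)
}
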