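# Synthetic mouse-face video generator.
#
# Emulates the three pain-dependent cues the grading pipeline relies on:
# orbital tightening (pupil radius decreasing with grade), face-wiping bouts
# of the forelimb (Poisson-rate events increasing with grade), and a facial
# texture/bulge pattern whose contrast increases with grade. Frames are
# grayscale in [0, 1] with the lateral face seen from the side: an elliptical
# eye with a circular dark pupil, an elongated forelimb capsule below it,
# a smooth background gradient, and a windowed sinusoidal cheek texture.

#' Scene parameters for the synthetic face generator
#'
#' @param image_size Side of the square frame in pixels (>= 32).
#' @param pain_grade Integer grade, 0 = NP, 1 = MP, 2 = HP.
#' @param pupil_radius_mean Mean pupil radius in pixels. Defaults decrease
#'   with grade (orbital tightening).
#' @param wipe_rate Expected number of forelimb face-wiping events per clip.
#'   Defaults increase with grade.
#' @param texture_amplitude Contrast of the cheek bulge texture in intensity
#'   units. Defaults increase with grade.
#' @param noise_sigma Standard deviation of additive pixel noise; also scales
#'   the relative jitter of the per-clip pupil radius around its mean.
#' @param wipe_duration Length of one wipe event in frames.
#' @param seed Integer seed; fully determines all randomness.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_size = 64L,
                         pain_grade = 0L,
                         pupil_radius_mean = NULL,
                         wipe_rate = NULL,
                         texture_amplitude = NULL,
                         noise_sigma = 0.02,
                         wipe_duration = 6L,
                         seed = 1L) {
  if (!pain_grade %in% 0:2) stop("pain_grade must be 0 (NP), 1 (MP) or 2 (HP)")
  if (image_size < 32L) stop("image_size must be at least 32 pixels")
  u <- image_size / 64
  # grade-conditional defaults (per-grade study conditions)
  if (is.null(pupil_radius_mean))
    pupil_radius_mean <- c(9, 7.5, 6)[pain_grade + 1L] * u
  if (is.null(wipe_rate)) wipe_rate <- c(0.5, 2, 4)[pain_grade + 1L]
  if (is.null(texture_amplitude))
    texture_amplitude <- c(0.05, 0.15, 0.25)[pain_grade + 1L]
  stopifnot_scalar(pupil_radius_mean, "pupil_radius_mean")
  stopifnot_scalar(wipe_rate, "wipe_rate")
  if (wipe_rate < 0) stop("wipe_rate must be non-negative")
  if (pupil_radius_mean <= 0) stop("pupil_radius_mean must be positive")
  # the eye ellipse must be able to contain the pupil
  if (pupil_radius_mean >= 0.22 * image_size)
    stop("image_size too small to place a pupil of this radius")
  structure(list(
    image_size = as.integer(image_size),
    pain_grade = as.integer(pain_grade),
    pupil_radius_mean = pupil_radius_mean,
    wipe_rate = wipe_rate,
    texture_amplitude = texture_amplitude,
    noise_sigma = noise_sigma,
    wipe_duration = as.integer(wipe_duration),
    seed = as.integer(seed)
  ), class = "scene_params")
}

# Scene geometry shared by the rasteriser and the keypoint writer.
scene_geometry <- function(params) {
  S <- params$image_size
  list(
    eye_cx = round(0.45 * S), eye_cy = round(0.40 * S),
    eye_a = 0.30 * S, eye_b = 0.24 * S,
    limb_p0 = c(0.15 * S, 0.88 * S),   # rear end (shoulder side)
    limb_p1_rest = c(0.50 * S, 0.72 * S),
    limb_p1_peak = c(0.52 * S, 0.34 * S),
    limb_halfwidth = 0.05 * S,
    tex_cx = 0.68 * S, tex_cy = 0.70 * S, tex_sd = 0.20 * S,
    tex_lambda = 0.12 * S
  )
}

# Per-clip latent state derived deterministically from the seed: pupil
# radius and the wipe-event start times.
clip_state <- function(params, n_frames = 10000L) {
  with_seed(derive_seed(params$seed, 101L), {
    z <- rnorm(1)
    radius <- params$pupil_radius_mean * (1 + params$noise_sigma * z)
    radius <- max(radius, 1)
    n_events <- rpois(1, params$wipe_rate)
    starts <- if (n_events > 0) sort(runif(n_events, 0, n_frames)) else numeric(0)
    list(radius = radius, wipe_starts = starts)
  })
}

# Wipe phase in [0, 1] at frame t (0 when no event is active).
wipe_phase <- function(state, t, duration) {
  ph <- 0
  for (s in state$wipe_starts) {
    if (t >= s && t < s + duration) ph <- max(ph, (t - s) / duration)
  }
  ph
}

limb_endpoints <- function(geom, phase) {
  sw <- sin(pi * phase)
  delta <- geom$limb_p1_peak - geom$limb_p1_rest
  p1 <- geom$limb_p1_rest + sw * delta
  p0 <- geom$limb_p0 + 0.3 * sw * delta
  list(p0 = p0, p1 = p1)
}

#' Generate one synthetic frame with its keypoint annotations
#'
#' Deterministic given `(params, t)`. Keypoints are returned in image pixel
#' coordinates (0-based, x rightward, y downward): the four pupil extrema
#' (top, bottom, left, right) and four forelimb landmarks (front end,
#' mid-front, mid-back, rear end).
#'
#' @param params A [scene_params()] object.
#' @param t Frame index (0-based).
#' @return List with `image` (image_size x image_size matrix in \[0, 1\],
#'   rows = y) and `keypoints` (8 x 2 matrix with rownames
#'   [keypoint_names()] and columns `x`, `y`).
#' @export
generate_frame <- function(params, t = 0L) {
  stopifnot(inherits(params, "scene_params"))
  generate_frame_impl(params, t, clip_state(params))
}

#' Generate a synthetic clip
#'
#' Wipe events are drawn from a Poisson process with rate `wipe_rate` per
#' clip; all randomness is derived from `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @param length Number of frames (>= 1).
#' @return Object of class `synthetic_clip`: list with `frames` (array
#'   T x S x S), `keypoints` (list of 8 x 2 matrices), `grade`, `params`.
#' @export
generate_clip <- function(params, length = 16L) {
  stopifnot(inherits(params, "scene_params"))
  if (length < 1L) stop("clip length must be >= 1")
  # wipe starts restricted to the clip's actual duration
  state <- clip_state(params, n_frames = length)
  frames <- array(0, dim = c(length, params$image_size, params$image_size))
  kps <- vector("list", length)
  for (t in seq_len(length) - 1L) {
    fr <- generate_frame_impl(params, t, state)
    frames[t + 1L, , ] <- fr$image
    kps[[t + 1L]] <- fr$keypoints
  }
  structure(list(frames = frames, keypoints = kps,
                 grade = params$pain_grade,
                 n_wipe_events = length(state$wipe_starts),
                 wipe_starts = state$wipe_starts,
                 pupil_radius = state$radius, params = params),
            class = "synthetic_clip")
}

# Rasterise one frame against an explicit clip state. generate_frame() uses
# the default event horizon so single frames are deterministic in
# (params, t) alone; generate_clip() restricts event times to the clip.
generate_frame_impl <- function(params, t, state) {
  S <- params$image_size
  geom <- scene_geometry(params)
  xs <- matrix(rep(0:(S - 1), each = S), nrow = S)
  ys <- matrix(rep(0:(S - 1), times = S), nrow = S)
  img <- 0.45 + 0.10 * ys / S
  win <- exp(-((xs - geom$tex_cx)^2 + (ys - geom$tex_cy)^2) /
               (2 * geom$tex_sd^2))
  img <- img + params$texture_amplitude *
    sin(2 * pi * xs / geom$tex_lambda) * sin(2 * pi * ys / geom$tex_lambda) * win
  in_eye <- ((xs - geom$eye_cx) / geom$eye_a)^2 +
    ((ys - geom$eye_cy) / geom$eye_b)^2 <= 1
  img[in_eye] <- 0.85
  r <- state$radius
  in_pupil <- (xs - geom$eye_cx)^2 + (ys - geom$eye_cy)^2 <= r^2
  img[in_pupil] <- 0.08
  ph <- wipe_phase(state, t, params$wipe_duration)
  ends <- limb_endpoints(geom, ph)
  v <- ends$p1 - ends$p0
  len2 <- sum(v^2)
  tt <- clamp(((xs - ends$p0[1]) * v[1] + (ys - ends$p0[2]) * v[2]) / len2, 0, 1)
  d2 <- (xs - (ends$p0[1] + tt * v[1]))^2 + (ys - (ends$p0[2] + tt * v[2]))^2
  img[d2 <= geom$limb_halfwidth^2] <- 0.25
  if (params$noise_sigma > 0) {
    noise <- with_seed(derive_seed(params$seed, 202L, t),
                       matrix(rnorm(S * S, 0, params$noise_sigma), S, S))
    img <- img + noise
  }
  img <- clamp(img, 0, 1)
  frac <- rbind(limb1 = 1, limb2 = 2 / 3, limb3 = 1 / 3, limb4 = 0)
  limb_pts <- cbind(ends$p0[1] + frac * v[1], ends$p0[2] + frac * v[2])
  kp <- rbind(
    pupil1 = c(geom$eye_cx, geom$eye_cy - r),
    pupil2 = c(geom$eye_cx, geom$eye_cy + r),
    pupil3 = c(geom$eye_cx - r, geom$eye_cy),
    pupil4 = c(geom$eye_cx + r, geom$eye_cy),
    limb_pts
  )
  colnames(kp) <- c("x", "y")
  rownames(kp) <- keypoint_names()
  list(image = img, keypoints = kp)
}

#' Generate a balanced labeled clip collection
#'
#' @param n_per_grade Number of clips per grade (>= 1).
#' @param params_by_grade Optional list of three `scene_params` templates
#'   (NP, MP, HP); defaults to the grade-conditional defaults of
#'   [scene_params()].
#' @param clip_length Frames per clip.
#' @param seed Master seed; per-clip seeds are derived from it and recorded
#'   in the manifest.
#' @param image_size Frame side when using default templates.
#' @return List with `clips` (list of `synthetic_clip`), `manifest`
#'   (data.frame: clip_id, grade, seed).
#' @export
generate_dataset <- function(n_per_grade, params_by_grade = NULL,
                             clip_length = 16L, seed = 1L, image_size = 64L) {
  if (n_per_grade < 1L) stop("n_per_grade must be >= 1")
  grades <- rep(0:2, each = n_per_grade)
  clips <- vector("list", length(grades))
  seeds <- integer(length(grades))
  for (i in seq_along(grades)) {
    g <- grades[i]
    si <- derive_seed(seed, 7L, i)
    seeds[i] <- si
    base <- if (!is.null(params_by_grade)) params_by_grade[[g + 1L]] else
      scene_params(image_size = image_size, pain_grade = g)
    p <- base
    p$seed <- si
    p$pain_grade <- as.integer(g)
    clips[[i]] <- generate_clip(p, clip_length)
  }
  manifest <- data.frame(clip_id = seq_along(grades) - 1L,
                         grade = grades, seed = seeds)
  list(clips = clips, manifest = manifest)
}

#' Write a synthetic clip as a PNG frame directory with a CSV annotation file
#'
#' Frames are written as `frame_0000.png`, ... plus `annotations.csv` with
#' columns `image_path`, `pupil1_x`, `pupil1_y`, ..., `limb4_y`, `grade`,
#' and a small JSON-like manifest `manifest.txt`.
#'
#' @param clip A `synthetic_clip`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the annotation data.frame.
#' @export
write_clip <- function(clip, dir) {
  stopifnot(inherits(clip, "synthetic_clip"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(clip$frames)[1]
  rows <- vector("list", n)
  for (t in seq_len(n)) {
    path <- file.path(dir, sprintf("frame_%04d.png", t - 1L))
    png::writePNG(clip$frames[t, , ], path)
    kp <- clip$keypoints[[t]]
    vals <- as.vector(t(kp))  # x1 y1 x2 y2 ...
    names(vals) <- paste0(rep(rownames(kp), each = 2), c("_x", "_y"))
    rows[[t]] <- data.frame(image_path = basename(path), t(vals),
                            grade = clip$grade)
  }
  ann <- do.call(rbind, rows)
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  writeLines(sprintf('{"n_frames": %d, "grade": %d, "image_size": %d, "seed": %d}',
                     n, clip$grade, clip$params$image_size, clip$params$seed),
             file.path(dir, "manifest.txt"))
  invisible(ann)
}

#' Synthetic fluorescence image stack with region masks
#'
#' Builds a stack in which the ROI disk carries
#' `baseline + signal_trace + ring_contamination`, the surrounding ring
#' carries `baseline + ring_contamination`, and the background sits at
#' `baseline`, plus optional Gaussian noise. The three masks are pairwise
#' disjoint by construction.
#'
#' @param baseline Scalar resting intensity (>= 0).
#' @param signal_trace Per-frame signal amplitude (>= 0); length sets the
#'   number of frames.
#' @param ring_contamination Per-frame contamination amplitude (scalar or
#'   per-frame, >= 0).
#' @param noise_sigma Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param side Frame side in pixels.
#' @param masks Optional list(roi, ring, background) of logical matrices to
#'   use instead of the built-in concentric layout; must be pairwise
#'   disjoint.
#' @return List with `stack` (T x side x side array) and `masks`
#'   (list of logical matrices `roi`, `ring`, `background`).
#' @export
generate_fluorescence_stack <- function(baseline, signal_trace,
                                        ring_contamination = 0,
                                        noise_sigma = 0, seed = 1L,
                                        side = 32L, masks = NULL) {
  if (baseline < 0 || any(signal_trace < 0) || any(ring_contamination < 0))
    stop("all intensities must be >= 0")
  Tn <- length(signal_trace)
  if (length(ring_contamination) == 1L)
    ring_contamination <- rep(ring_contamination, Tn)
  if (length(ring_contamination) != Tn)
    stop("ring_contamination must be scalar or match signal_trace length")
  if (is.null(masks)) {
    cx <- (side - 1) / 2
    xs <- matrix(rep(0:(side - 1), each = side), nrow = side)
    ys <- matrix(rep(0:(side - 1), times = side), nrow = side)
    rr <- sqrt((xs - cx)^2 + (ys - cx)^2)
    masks <- list(roi = rr <= side / 6,
                  ring = rr > side / 6 + 1 & rr <= side / 4,
                  background = rr > side / 3)
  }
  if (any(masks$roi & masks$ring) || any(masks$roi & masks$background) ||
      any(masks$ring & masks$background))
    stop("region masks must be pairwise disjoint")
  if (!any(masks$roi) || !any(masks$ring) || !any(masks$background))
    stop("each region mask must be nonempty")
  stack <- array(baseline, dim = c(Tn, side, side))
  for (t in seq_len(Tn)) {
    frame <- matrix(baseline, side, side)
    frame[masks$ring] <- baseline + ring_contamination[t]
    frame[masks$roi] <- baseline + signal_trace[t] + ring_contamination[t]
    if (noise_sigma > 0) {
      frame <- frame + with_seed(derive_seed(seed, 303L, t),
                                 matrix(rnorm(side * side, 0, noise_sigma),
                                        side, side))
    }
    stack[t, , ] <- frame
  }
  list(stack = stack, masks = masks)
}

#' @export
print.synthetic_clip <- function(x, ...) {
  cat(sprintf("<synthetic_clip> %d frames of %dx%d, grade %d (%s)\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              x$grade, names(pain_grades())[x$grade + 1L]))
  invisible(x)
}
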