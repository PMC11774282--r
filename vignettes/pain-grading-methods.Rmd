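---
title: "Methods: two-channel pain grading for mouse facial video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-channel pain grading for mouse facial video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`painface` implements an objective, video-based grading of trigeminal pain
in head-fixed mice into three classes — no pain (NP, 0), moderate pain
(MP, 1) and high pain (HP, 2). The grading model has two parallel
channels:

* a **keypoint channel** (`kpnet`): a residual backbone with eight
  transposed-convolution heads that emit one score map per facial
  landmark (four pupil boundary points, four forelimb points). A readout
  layer converts each map to coordinates. This channel carries the
  *dynamic behavioural* cues: orbital tightening (pupil size) and
  face-wiping forelimb motion.
* a **texture channel** (`cnn3d`): six shape-preserving 3-D convolutions
  with three 2×2×2 max pools and a 16-dimensional fully connected
  feature layer, consuming a short clip. This channel carries the
  *static texture* cues of the face (bulge contrast and its evolution).

The two channels are fused by **fixed model reuse**: the trained keypoint
network is frozen, its eight readout coordinates are flattened into a
16-vector, concatenated with the 16-dimensional texture feature into a
1 × 32 fused vector, and a single affine layer + softmax yields the
three class probabilities. During fused training only the texture channel
and the fusion head are updated; the keypoint channel's parameters are
checksummed before and after as a hard contract.

The package also implements the two assays that define the objective
ground truth: infraorbital-nerve ΔF/F from fluorescence stacks, and the
up-and-down von Frey facial threshold procedure, together with the image
preprocessing pipeline and the evaluation metrics.

# The assay machinery

## ΔF/F (`compute_dff`)

Given the per-frame ROI mean `F_raw`, the per-frame mean over a ring
around the ROI `F_ring`, and the scalar background baseline `F_b`
(minimum of the stack restricted to a background region):

```
F_ROI = F_raw - F_b
F_con = F_ring - F_b          # out-of-focus contamination estimate
F_sig = F_ROI - alpha * F_con # alpha = 0.9 by default
dFF   = F_sig / F0
```

`F0` is the mean of `F_ROI` over a configurable baseline window; the
default is the whole trace because the baseline estimator is described
only as an average of `F_ROI`. The contamination coefficient `alpha` is
exposed with default 0.9. Two numerical conventions are worth stating:

* the background statistic is the *global minimum* of the masked stack,
  not a per-frame minimum;
* if `F0 <= 0` the computation stops with an error naming the estimate,
  except in the fully degenerate case `F_sig ≡ 0` (a flat record), for
  which `dFF` is defined as the zero trace. This keeps the null-signal
  case well defined without hiding genuinely broken baselines.

ΔF/F is invariant under a global intensity rescaling (all of `F_raw`,
`F_ring`, `F_b` multiplied by `c > 0`), and strictly increasing in
`F_raw`; both properties are enforced by tests, and the trace-level
computation is tested against a per-pixel brute-force recomputation at
tolerance 1e-9.

## Up-and-down threshold (`run_updown`)

The filament series defaults to 0.02, 0.04, 0.07, 0.16, 0.4, 0.6, 1.0
and 1.4 g. Starting from the smallest filament, a negative response (O)
steps up, a positive response (X) steps down, clamped at the series
ends. After the first adjacent "OX" or "XO" pair, exactly four further
stimulations are applied under the same rule. The threshold is the
smallest force with a positive response in the window that starts at the
second element of the reversal pair — the least force that reliably
evokes withdrawal. The classical Dixon 50% estimator is deliberately not
used: the procedure here records a filament size, not an interpolated
force. A responder that never reverses (always O, or always X from the
lowest filament) is an error after a 50-stimulation cap rather than an
endless loop; real protocols would record such an animal as off-scale.

Saline concentration maps to grade with no interpolation: 0.9% → NP;
6%, 12%, 18% → MP; 25%, 30% → HP. Unknown concentrations are errors.

# The networks

## Keypoint channel

The full-scale configuration uses a ResNet-50 backbone at input 512 with
stage strides 2-2-2-2-1, giving the feature ladder 256² × 64, 128² × 256,
64² × 512, 32² × 1024, 32² × 2048, then eight transposed-convolution
heads (kernel 4, stride 2, pad 1) produce 64 × 64 score maps — one per
keypoint, at stride 8 relative to the input. No max pool follows the
stem: the printed stride column alone reproduces the ladder, so the
first block of each downsampling stage carries stride 2.

Training targets are binary disks: a map cell is positive iff its centre
(`x = col·stride + stride/2`) lies within `positive_radius` (default 5,
Euclidean) input pixels of the keypoint. The loss is per-pixel sigmoid
binary cross-entropy; positives are re-weighted (`pos_weight`, default
20) because a 5-pixel disk covers a small fraction of the map. The
readout is arg-max with deterministic tie-breaking toward the smallest
(y, x); a soft-argmax (`readout = "soft"`) provides sub-cell accuracy
and differentiability. Backbone initialisation is seeded fan-in uniform;
a warm start from a weights file is available behind a flag, and random
initialisation is the default so nothing is downloaded.

A reduced `small_residual` backbone (same stride pattern, ≤ 64 channels,
configurable overall stride) is the practical choice for CPU training;
the full Table-geometry remains available and its ladder is asserted
layer by layer in the tests via the closed-form shape calculator
`kpnet_shapes()`.

## Texture channel

Six 3-D convolutions (default kernels 3 × 3 × 3, channel plan
32-32-64-64-128-128), ReLU, 2×2×2 max pool after layers 2, 4 and 6,
flatten, fully connected to 16, softmax to 3. `temporal_depth`
parameterises the input clip length (a 16-frame clip has temporal extent
2 after the third pool); the convolution kernels keep their own temporal
extent. The spatial kernel side is sweepable (3–11) with anisotropic
same padding, and `cnn3d_sweep()` implements the kernel-size ×
temporal-depth accuracy grid with seeded repetitions, mirroring the
published sweep design. Training is seeded SGD with momentum on the
categorical cross-entropy, initial learning rate 1e-4, batch 16, with an
internal seeded 80/20 split.

Temporal depths that are not divisible by 8 cannot pass three 2×
temporal poolings; the configuration rejects them explicitly rather than
silently truncating.

## Fusion

`train_painnet()` takes the *pre-trained, frozen* keypoint network and a
texture channel (fresh, or warm-started from a trained `cnn3d` — the
cascade order in which the two channels are trained first and then
fused). Because the keypoint channel is frozen, its per-clip readout
vectors are precomputed once. Keypoint coordinates are normalised to
[0, 1] before fusion by default so the head is scale-free; raw-pixel
mode exists for fidelity. Which frame feeds the keypoint channel is
configurable: `"last"` (default) or `"mean"` (readout vectors averaged
over all frames). The mean option matters whenever single frames can be
corrupted — in the synthetic study the forelimb periodically occludes
the eye mid-wipe, and averaging over the clip keeps the pupil cue
available; real video has the same failure mode (blinks, grooming).

Fused training proceeds in two phases:

1. **Head pre-training.** The 32 → 3 affine head is fitted on the fused
   features of the initial trunk as a convex multinomial-logistic
   problem: full-batch gradient descent with momentum, per-feature
   standardisation (folded back into the affine weights afterwards, so
   the head remains a plain affine layer over the raw fused vector) and
   a mild L2 penalty (1e-4). Standardisation is what lets the head
   exploit coordinate contrasts of a few hundredths in normalised units.
2. **Joint fine-tuning.** Texture trunk and head are updated jointly by
   seeded minibatch SGD at learning rate 1e-4 with global gradient-norm
   clipping (0.5). The pre-trained head makes the fused loss surface
   steep, so unclipped joint steps oscillate; clipping keeps the phase a
   gentle refinement.

A fresh random head trained jointly from the start destroys the
warm-started trunk before it can learn — this failure mode is why the
phases exist, and the frozen-keypoint contract is asserted with both an
exact parameter comparison and a checksum.

# Synthetic study conditions

No recordings are distributable, so every test runs on the package's own
generator, which emulates the three pain-dependent cues at their
simplest useful geometry: a bright elliptical eye with a circular dark
pupil whose radius decreases with grade (9, 7.5, 6 px at the 64-px
reference scale), a forelimb capsule that sweeps an arc over the eye
during Poisson-rate wipe events (0.5, 2, 4 expected events per clip by
grade), and a Gaussian-windowed sinusoidal cheek texture whose contrast
increases with grade (0.05, 0.15, 0.25). Pixel noise is additive
Gaussian (default sd 0.02), and the per-clip pupil radius jitters with
the same parameter so that zero noise means exactly reproducible
geometry. Every random quantity derives from one integer seed per clip;
annotations are written analytically from the same geometry that is
rasterised, so keypoint ground truth is exact by construction.

The **channel-split study** used for the fusion experiments assigns each
channel only part of the grade information: pupil radius separates NP
from MP/HP (9 vs 6.5 px — a fine geometric cue the keypoint channel
reads precisely at 64 px), and texture amplitude separates HP from NP/MP
(0.08 vs 0.22 — a coarse contrast cue that survives the texture
channel's three poolings at its 16-px input, where sub-pixel pupil
differences are mostly lost). Each single channel therefore faces a
~2/3 accuracy ceiling while the fused model can separate all three
grades; the tests assert the qualitative ordering (fused not behind the
best single channel), not any published number.

What the generator does *not* model: fur and whisker texture, grimace
action units beyond a contrast knob, illumination changes, camera
motion, inter-animal variability, or label noise. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that
the architecture can exploit the cue structure it was designed for —
not that the published accuracy transfers to real animals.

# Problem sizes and numerical choices

The test suite and the acceptance script train at reduced scale, chosen
so the full pipeline runs comfortably on a single CPU: keypoint network
at 64 × 64 with the `small_residual` backbone (overall stride 4,
soft-argmax readout, 250 SGD iterations, batch 8, lr 0.05, 75 frames
drawn from clips so wipe poses are represented); texture channel on
8-frame clips at 16 × 16 with channel plan 4-4-8-8-16-16 (25 epochs,
lr 0.01); fusion on 90 clips (30 per grade, 80/20 split), repeated over
three derived seeds and averaged. The full-scale configurations are
instantiated and shape-checked but not trained.

Other numerical conventions: coordinates are 0-based with x rightward
and y downward; cell-centre back-mapping is `x = col·stride +
stride/2`; arg-max ties break toward the smallest (y, x); invisible
keypoints (NA coordinates) produce all-zero target maps; weight
initialisation is seeded fan-in uniform (limit `sqrt(6/fan_in)`);
`.Random.seed` is saved and restored around every seeded internal, so
library calls never disturb the caller's RNG stream.

# Known limitations

* The readout arg-max is not differentiable; the keypoint channel is
  trained purely through its score-map loss (the soft-argmax option
  exists for end-to-end experiments but is not used in training).
* The sequence mean-squared-error `E = (1/K) Σ ‖ô_k − o_k‖²` is
  provided as a standalone metric (`sequence_mse`); its role inside the
  original training procedure is not specified anywhere we could pin
  down, so it enters no loss here.
* Macro averaging is used for precision/recall/F1 and one-vs-rest AUC;
  with balanced classes micro and macro nearly coincide, and a micro
  flag is available.
* The blur-rejection criterion (variance of Laplacian with an absolute
  threshold) and the ring-region geometry are operationalisations; both
  are configurable because no published criterion exists for either.
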