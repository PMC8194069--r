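---
title: "poseflow: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poseflow: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the label model, the evaluation metric, the temporal aggregation stage, the
two-view correction, and the synthetic scenes everything is validated on —
together with the numerical choices a maintainer would want written down.

## 1. Heatmap labels

A human annotation is a keypoint location $(x, y)$ (float pixels, 0-based,
x = column, y = row, origin top-left) plus an acceptance box of
`box_w × box_h` pixels. The label for one keypoint is built in three steps:

1. evaluate an axis-aligned 2D Gaussian PDF at the centres of the pixels
   inside the box (hard zero outside — the "truncation"), centred at the
   float annotation;
2. rescale so the maximum is exactly 1.0;
3. set every value strictly below 0.1 to 0.

The nonzero support that survives step 3 *is* the correctness region of the
evaluation metric (section 2), which is why the box, chosen per keypoint by
the annotator to match the keypoint's physical extent, matters more than
the Gaussian shape itself.

Choices the label model leaves open, and what this package does:

* **Gaussian width.** σ = 0.25 × box dimension per axis, so the box spans
  roughly ±2σ. This keeps the truncated tail small while leaving most of
  the box above the 0.1 cut. It is a package convention, configurable via
  `sigma_frac`.
* **Box placement.** The box is centred on the nearest pixel to the float
  annotation (round half up); even box sizes extend one pixel further
  right/down. Boxes are clipped to the image.
* **Peak pixel.** The Gaussian mean sits at the float coordinate, so the
  discrete maximum lands on the nearest pixel.
* **Boundary rule.** A pixel holding exactly 0.1 after thresholding is
  inside the support: the rule zeroes only values *strictly* smaller
  than 0.1.
* **Missing keypoints** in a frame produce all-zero grids, flagged in the
  stack metadata and excluded from aPCK denominators.

For training targets the label stack is multiplied by a peak value
(default 16) to increase contrast between label region and background, and
replicated once per intermediate-supervision stage; evaluation-side labels
are never scaled.

## 2. aPCK and RMSE

`apckErrorTable()` counts a prediction correct iff its nearest pixel
(round half up; outside the image counts as incorrect) has a positive label
value, and reports per-keypoint error rates `1 − n_correct / n_evaluated`
plus their unweighted mean and SD across keypoints. Pooling is per keypoint
over all evaluated frames; frames where a keypoint is absent are excluded
from that keypoint's denominator. This absent-keypoint rule is a package
convention (rarely-visible keypoints motivate it); it is documented rather
than inferred. `rmseTable()` gives the per-keypoint root-mean-square
Euclidean distance in pixels for comparison, and `pairedKeypointTest()`
wraps the paired-by-keypoint t-test used to compare two models.

## 3. Temporal aggregation

For target frame $t$, window of $2f+1$ indices $t + ks$, $k = -f..f$
(defaults $s = 1$, $f = 4$; at sequence edges indices clamp to the valid
range, replicating boundary frames so output length equals input length).
Each neighbour's heatmaps are morphed onto the target frame through dense
optical flow, then combined by a per-keypoint weighted sum.

**Flow.** Farnebäck polynomial expansion, implemented in C++ behind
`denseFlow()`: each image is locally fitted by a quadratic form under a
Gaussian applicability (neighbourhood 7 px, σ 1.5); displacement is solved
coarse-to-fine over an image pyramid (scale 0.5, 5 levels, 8 iterations per
level) with a 27 px normalized box window accumulating the per-pixel normal
equations. These hyperparameters are the package defaults
(`FarnebackParams()`). Numerical guards: pyramid levels stop when a level
would be smaller than `poly_n + 2`; near-singular 2×2 systems
(determinant < 1e-12) keep the previous estimate; displacements are clamped
to the image diagonal, so the field is finite even on blank frames.

* **Flow direction.** Flow is computed with the *target* as reference, so
  warping is backward sampling — every output pixel pulls from a source
  location, leaving no holes. The alternative (forward splatting) produces
  cracks and was rejected.
* **Warping.** Bilinear; taps outside the grid contribute 0 — heatmaps are
  confidence mass and the border must not fabricate any.
* **Colour.** Multi-channel frames are reduced to Rec.601 luminance before
  flow; flow is computed on the (preprocessed) video frames, not on model
  feature maps.

**Aggregation.** One weight vector per keypoint over the window offsets —
the "1 × 1 convolution" — with no bias and no nonlinearity:
$y_p = \sum_k w_{pk} o^k_p$ pixelwise. Weights are *not* shared across
keypoints: keypoints differ in motion statistics (a paw swings faster than
a snout), and per-keypoint mixing lets each learn its own temporal
profile. Mixing information *across* keypoints is a defensible alternative
reading of the aggregation layer; it was rejected to keep the fitted
parameters interpretable and the solve exact. Negative aggregate values
are clipped to 0 only for decoding and serialisation; raw values are kept
during training.

**Fitting.** Two solvers, which the test suite requires to agree:

* *Least squares* (default): per keypoint, the window weights solve the
  normal equations accumulated streamingly over training windows
  (`A += XᵀX`, `b += Xᵀy` per window, one 9×9 solve at the end). Rank
  deficiency — e.g. a static scene where all window members are identical —
  falls back to the minimum-norm SVD solution with a warning.
* *Stochastic ADAM*: β₁ = 0.9, β₂ = 0.999, learning rate 1e-4, 30 epochs,
  one update per training window per epoch, weights initialised uniformly
  at 1/(2f+1). The update granularity matters: a full-batch reading of
  "30 epochs" would allow only 30 steps, far too few to traverse the
  O(0.1) distances involved; per-window stochastic updates mirror how such
  models are trained in practice.

Labels enter the fit peak-scaled (section 1); the mock predictor renders
its peaks at the same scale, so fitted weights stay O(1/(2f+1)) under
either solver.

## 4. Multi-view correction

For rigs where two views share the x-axis, the better-predicting view
constrains the other. Candidates are local maxima of the Gaussian-smoothed
heatmap (default `smooth_sigma` 3 px, `min_rel` 0.1 — both package
defaults, not prescribed by the method), strictly greater than their 8
neighbours and at least `min_rel` of the global maximum, which is always
included. The corrected location is the candidate minimising
$|x_{cand} - x_{ref}|$. Ties break to the higher score, then the smaller
row-major index. A keypoint with no candidates keeps its location and is
flagged. The supplied reference locations are used as-is (truth, raw
argmax, or that view's own corrected output — the caller decides).
Correction never increases $|x - x_{ref}|$; this is asserted as an
invariant.

## 5. The synthetic scenes

`SceneSpec()`/`simulateSequence()` generate the study conditions the
package is validated under: P Gaussian blobs (σ 3 px) following sinusoidal
trajectories (gait-like swing along x with a smaller quadrature bob along
y, speeds ~1–2 px/frame) over a weakly textured static background
(smoothed fixed-pattern noise, amplitude 0.1 — flat backgrounds make dense
flow ill-posed), with per-frame Gaussian sensor noise (σ 0.01) and
occlusion episodes during which a grey rectangle covers the keypoint
(masking keeps frames photometrically plausible; deleting the blob would
not). Annotation boxes are fixed at 4 × blob σ. All randomness derives
from the single spec seed through per-purpose substreams; identical specs
give bit-identical output. Trajectories must stay 3 blob-σ inside the
frame; the spec validity check rejects escapes.

The standard presets (`standardScenarios()`): 96 × 96 px, P = 4, 500
frames for the temporal experiments; `isolated-errors` pairs the gait
scene with a mock predictor committing isolated single-frame gross errors
(probability 0.15 per frame per keypoint, displacement 40 px, pairwise
non-adjacent), `error-runs` uses runs of 9 consecutive error frames —
longer than the aggregation window — to exercise the method's documented
limitation; `static` (120 frames, zero motion and noise) is the null
control; `two-view-swap` (200 frames) injects x-displaced primary peaks
that retain a truthful secondary peak, the paw-swap failure mode, against
a perfect bottom-view reference.

What the simulator does **not** emulate: deformable bodies, appearance
change, lighting variation, motion blur, camera shake, multi-animal
identity ambiguity, and base-model error correlated with appearance rather
than injected by schedule. Passing tests therefore demonstrate that the
temporal and multi-view machinery is correct and effective under its
stated assumptions — not that any particular accuracy will transfer to a
specific animal dataset.

## 6. Mock predictor and the base-model contract

`mockPredict()` stands in for a trained single-frame model: per keypoint
it re-renders a Gaussian peak (σ 3 px, amplitude = training peak 16) at
the true location jittered by `loc_noise_sigma`; with probability
`error_prob` — and always under occlusion — the peak is displaced by
`error_displacement` px in a seeded direction kept inside the image.
Draws are reproducible per (seed, frame id, keypoint), so experiments are
exactly repeatable frame by frame. Real predictors plug in behind
`validatePredictions()` (image-sized, finite, non-negative grids in the
dataset's keypoint order) and the persisted stack formats. The deep
baseline itself (ResNet-backed encoder, transposed-convolution decoder
with 13 × 13 kernels, final filter count = P, optional intermediate
supervision; MSE loss, ADAM lr 1e-4, 50 epochs, batch 10) is deliberately
configuration-only (`readBaselineConfig()`): GPU-scale training is outside
this package's desk-scale contract, and nothing in the temporal or
multi-view stages depends on it. The relative weighting of an
intermediate-supervision loss against the final head is left to external
implementers.

## 7. Preprocessing

* **Split**: seeded permutation with largest-remainder sizing (0.6/0.2/0.2
  by default, the 3:1:1 split; 500 ids give exactly 300/100/100).
  Frame-level by default; `group_by = "video"` keeps each video whole and
  balances greedily toward the target counts — the mechanism for keeping
  individuals out of the training set.
* **Rotation**: expanded canvas (axis-aligned bounding box of the rotated
  image), zero padding, bilinear resampling; annotations are mapped by the
  exact affine transform, box sizes unchanged. Positive angles are
  clockwise on screen (y down).
* **Flips**: exact mirrors (`x → W−1−x` etc.); an optional user-supplied
  bijective swap map exchanges bilaterally symmetric keypoint names. The
  default is no swapping — whether flips should relabel left/right is
  dataset-specific and deliberately left to the caller.
* **Resizing**: pixel-area relation when shrinking (each output pixel is
  the exact area average of the region it covers — the preferred
  decimation resampler), bilinear when enlarging; coordinates and box
  dimensions scale by `out/in` per axis, boxes floored at 1 px.
* **Random augmentation**: rotation angle uniform in (−10°, +10°) by
  default; each admissible flip applied with probability 0.5; all draws
  from per-(seed, index) substreams.

## 8. Problem sizes and runtime

The test suite and the acceptance script run everything at the preset
sizes: 500-frame, 4-keypoint, 96 × 96 sequences for the temporal
experiments (isolated errors on five seeds, error runs on two), 160
frames / 120 training windows for the solver-agreement check, 200 frames
for the two-view experiment, and 100–1,000 randomized cases for the
label/metric oracles. One temporal experiment is ≈4,500 flow computations
(~6 ms each in the compiled core); a full experiment takes about a minute
on one CPU, the whole suite a few minutes.

## 9. Known limitations

* Temporal aggregation cannot repair error runs spanning the window — by
  design it only *smooths against* its neighbours; the error-runs test
  asserts no catastrophic degradation, not improvement.
* Backward warping assumes flow is locally accurate near heatmap mass; on
  textureless regions flow is unconstrained (guarded, but uninformative).
* Multi-view correction requires the truthful peak to survive in the
  heatmap as a local maximum above `min_rel`; a base model that assigns
  the true location no mass at all cannot be corrected.
* The shared-axis geometry is exactly two views; triangulation and
  reprojection across three or more calibrated cameras is out of scope.
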