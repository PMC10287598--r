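---
title: "Two-branch microcalcification segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-branch microcalcification segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcseg)
```

Microcalcifications (MCs) are sub-millimetre calcium deposits that appear
as tiny bright structures on digital mammograms; their morphology and
distribution inform cancer suspicion. mcseg segments individual MCs on 2-D
mammograms with two complementary branches, then quantifies their
morphology for downstream malignancy classification. This vignette
describes the models, their assumptions, the parameters that matter, the
numerical choices made where the design was open, and what the synthetic
phantoms do and do not establish.

## The blob branch: Hessian-constrained multiscale DoG

An image `I(x, y)`, normalized to `[0, 1]`, is embedded in a Gaussian
scale space `L(x, y; sigma) = G(sigma) * I` over a geometric scale ladder
`sigma_n = k^n sigma_min` (defaults `sigma_min = 1.18` px,
`sigma_max = 3.1` px). The ratio `k` is not a reported constant of the
method; the package defaults to `k = 2^(1/3)` — three scales per octave,
the standard choice in DoG blob detection — which yields the six scales
1.18, 1.49, 1.87, 2.36, 2.97, 3.75 px. Adjacent planes are combined into a
scale-normalized difference of Gaussians,

```
DoG(x, y, n) = sigma_n / (sigma_{n+1} - sigma_n) * (L(sigma_n) - L(sigma_{n+1})),
```

oriented so that a bright blob produces a *positive* response at its
center. (The sign convention matters: only with this orientation does a
positive response floor `T_DoG` combined with 3-D *maxima* detection find
bright structures, and only then is the Hessian of the DoG negative
definite at blob centers, as the constraint below requires.) Blobs are the
26-neighborhood local maxima of the `(scale, row, col)` volume after
suppressing responses below `T_DoG = 0.006`; the threshold presumes the
`[0, 1]` intensity scale, which is why normalization precedes the scale
space. A voxel qualifies if it is `>=` all existing neighbors and `>` at
least one; within an equal-valued connected plateau the lexicographically
smallest `(scale, row, col)` voxel is kept, making the detector
deterministic and exactly reproducible by an exhaustive scan (a property
the test suite asserts on small stacks). Maxima on the first and last
scale plane are allowed: the scale range is deliberately narrow and
discarding edge planes would lose the smallest MCs.

Overlapping blobs are pruned by treating each as a disc of radius
`sqrt(2) sigma` (the radius of a binary disc whose DoG response peaks at
scale `sigma`): when the intersection exceeds fraction `O_DoG` of the
smaller disc, the smaller-sigma blob is removed. The operating default
`O_DoG = 1` never satisfies the strict inequality, i.e. pruning is
disabled; the machinery is exercised at other settings in tests.

Each surviving blob is delineated at its own scale with a convexity
constraint on the Hessian of the DoG plane,

```
tr(H) < 0  and  ( det(H) < 0  or  det(H) / tr(H)^2 <= h_thr ),
```

which admits bright blob-like structures (both eigenvalues negative) and
bright tubular ones (one large negative, one small eigenvalue). Second
derivatives are central finite differences with reflective borders, the
same border policy as the convolutions. Division by `tr(H)^2` is guarded:
at `tr(H) = 0` the first clause already fails. One consequence worth
stating plainly: with `det(H) >= 0` and `tr(H) < 0` the ratio is
analytically at most 1/4, so any `h_thr >= 0.25` — including the operating
default `h_thr = 1.4` — reduces the whole constraint to `tr(H) < 0`. The
implementation still evaluates the constraint literally, and a property
test pins the equivalence. The blob's object is the 8-connected component
of the constraint mask containing the blob location (8-connectivity
because MCs are tiny and 4-connectivity fragments diagonal structures); a
blob whose seed pixel fails the constraint is dropped rather than snapped
to the nearest component — conservative and deterministic. All objects are
unioned into one binary mask.

## The regression branch: proximity maps and a pyramid network

Reference annotations mix single-pixel locations (small MCs) with closed
contours (larger ones). Both are rasterized — contours filled
boundary-inclusively — into `M(x, y)` and converted to a proximity map

```
P(x, y) = max_i g(r_i),   g(r) = (exp(alpha (1 - r/xi)) - 1) / (exp(alpha) - 1)
```

for `r <= xi`, else 0, with `r_i` the Euclidean distance to annotated
pixel `i`. `g` decays from 1 at the annotation to 0 at distance `xi`
(default `xi = 10` px, `alpha = 1`; as `alpha -> 0` the kernel approaches
the linear ramp `1 - r/xi`, and `alpha = 0` itself is rejected as
undefined). Every foreground pixel is a source, so contour interiors sit
at `P = 1` and the decay extends `xi` beyond the boundary. Because `g` is
decreasing in `r`, the maximum over sources is `g` at the nearest source,
so the map is computed with one exact Euclidean distance transform; a
brute-force test confirms the equivalence.

The regressor is a fully convolutional pyramid network: an encoder
exposing features at strides 4, 8, 16, and 32; per-level 1x1 convolutions;
upsampling by 1, 2, 4, and 8 to the stride-4 grid; elementwise summation;
spatial dropout (training only); further convolutions; bilinear x4
upsampling to the input size; and a sigmoid. Training minimizes the soft
Dice loss

```
L(Phat, P) = 1 - (2 sum P Phat + eps) / (sum (P + Phat) + eps),  eps = 1,
```

with Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`). Patches are
extracted by a 512/480 sliding window (plus flush-to-border windows so the
image strip beyond the last regular offset is covered — the bare 512/480
grid would leave it unseen), keeping only windows containing annotations,
and augmented to 320 x 320 with horizontal flips, magnification
(0.9–1.1), translations (up to 32 px), cropping, and image-only contrast
(x0.9–1.1), brightness (±10%), and gamma (0.8–1.25) adjustments. The
augmentation magnitudes are package defaults, stated so they are
reproducible, and all configurable. After each epoch the model is scored
by mean IoU per validation patch at the best cut-off of a threshold sweep,
and the best epoch's weights are kept.

The network itself is implemented in base R with hand-written backward
passes (im2col convolutions, average pooling, nearest and bilinear
upsampling, spatial dropout, sigmoid), verified against numerical
differentiation to ~1e-9 relative error. The provided encoder is a small
4-stage convolutional network ("tiny"); its width (`channels`,
`decoder_channels`) is the capacity knob. A large pretrained encoder is
out of scope — classification-grade backbones and their pretraining data
are not part of this package — so published full-scale scores are not
reproducible here; the tiny encoder preserves the architecture's contract
(stride pyramid, decoder, loss, training protocol) at desk scale. For
desk-scale training the defaults are `lr = 3e-3`, no dropout, 40–60
epochs, with global gradient-norm clipping at 5: small-batch Dice
training occasionally produces step spikes that destabilize Adam at these
learning rates, and clipping removes that failure mode without changing
the converged solutions.

Full images are predicted by tiling (reflect-padded to the tile grid,
overlaps averaged), which preserves constants exactly and matches the
single-pass result on one-tile images.

## Fusion

The region mask `Phat >= p_thr` selects where MCs are likely; blob
objects whose pixel overlap with the region is at least `o_thr = 0.3` are
retained *with their full extent*. Clipping objects to the region would
corrupt the shape features computed downstream, which is the method's
point. The overlap boundary is `>=` (an object at exactly 30% overlap is
kept); a strict-mode flag provides the `>` variant.

## Evaluation protocols

Detection uses free-response ROC: for each `p_thr` in a sweep, fusion is
re-run, predictions are matched to ground truth, TPR is pooled over images
(`sum TP / sum truth objects`), and false positives are normalized by the
total imaged area in cm^2 (`rows x cols x spacing_mm^2 / 100` per image;
at 0.070 mm/px, 1 cm^2 is about 142.86^2 px). A prediction matches a truth
object if their centroids are within 5 px (0.35 mm) — boundary inclusive —
or their IoU is at least 0.3; matching is greedy one-to-one in ascending
centroid distance, which an audit against optimal assignment shows is
near-always optimal on small scenes. Truth objects may be bare points
(their own centroid, no pixel set). The partial AUC integrates TPR over
0–1 FP/cm^2 (trapezoidal, linear interpolation, constant extrapolation at
the ends) and is normalized by the range width so a perfect detector
scores 1; confidence intervals come from 100 bootstrap resamples of
images (percentile 2.5/97.5). The operating point is the sweep threshold
closest to `(0 FP/cm^2, TPR 1)`, ties resolved to the larger threshold.
Segmentation quality is reported as mean IoU per image (average of
foreground and background class IoU) and IoU per object (each truth
object against the prediction object with the largest intersection, zero
if none, averaged; IoU of two empty masks is defined as 1).

Pooling choices the protocol leaves open were fixed once: TPR is pooled
across images rather than averaged per image (consistent with
area-normalized false positives), and the FROC sweep varies `p_thr` with
the blob branch fixed.

## The case study: 31 features and patient-wise classification

Regions of interest are fixed 256 x 256 crops centered on annotated
bounding boxes (shifted minimally at borders to stay inside the image;
fixing the size removes annotation-style bias and keeps the classifier
focused on segmentation-derived features). From each ROI's segmentation,
31 features are computed: 17 regional — foreground area, convex hull
area, ellipse-equivalent major/minor axis, orientation of the major axis
in (−90°, 90°] w.r.t. the row axis, eccentricity, solidity, the two
eigenvalues of the central second-moment tensor ("moments of inertia"),
the seven Hu invariant moments of the binary union mask, and the object
count — and 14 per-object aggregates, the mean and standard deviation
over 8-connected components of area, major/minor axis, maximum, minimum,
and mean normalized intensity, and eccentricity (a single object
contributes standard deviation 0). Hu moments are computed on the binary
mask, not intensity-weighted, and intensity statistics use normalized
intensities — both choices keep the features scale-free. An empty
segmentation yields a fully missing vector.

Classification is gradient tree boosting (depth 3, 200 trees, learning
rate 0.1 — explicit defaults, all configurable) under fivefold
patient-wise cross-validation: patients, not ROIs, are assigned to folds,
so no patient appears on both sides of a split. Imputation means and
standardization parameters are fit on training rows only. Per fold the
report gives the rank-based ROC AUC (tied scores count one half, so
constant scores give exactly 0.5) and, at the score threshold whose
sensitivity is closest to 0.9, accuracy, sensitivity, specificity, and
PPV; means and standard deviations are taken across folds.

## The phantom module

Because the clinical datasets cannot ship with the package, every stage is
exercised on synthetic phantoms: Gaussian-filtered white noise rescaled to
a mid-gray band (0.2–0.6) with correlation length 24 px plus independent
pixel noise (sd 0.01) emulates low-frequency breast texture; planted
objects are isotropic Gaussian spots (widths 1.5–2.5 px, amplitudes
0.3–0.5 — a few-sigma contrast typical of conspicuous MCs), anisotropic
ridges (vessel-like tubes), and filled super-ellipses for large
contour-annotated calcifications. The ground-truth boundary of every
object is the half-maximum level set of its own signal — unambiguous and
analytically checkable (a width-`s` spot has half-max radius
`s sqrt(2 ln 2)`). Objects with equivalent diameter under 10 px are
annotated by their center point, larger ones by a contour, mirroring the
mixed annotation style of MC datasets whose small/large convention is
itself unreported. Object centers are kept 4 half-widths apart unless
overlap is requested, and all randomness flows through explicit seeds, so
a configuration is bit-reproducible.

What phantom results do show: the blob branch localizes spot-like objects
to sub-pixel centroid accuracy; fusion removes detections outside the
region mask; the regressor can learn the proximity target from twenty
64 x 64 patches (mean IoU per patch ≥ 0.3 against half-max truth versus
≤ 0.05 untrained); the metrics obey their closed forms. What they do not
show: performance on real mammograms — phantoms lack ductal structure,
overlapping dense tissue, detector artifacts, and the intensity statistics
of real MC clusters, so phantom detection rates are upper bounds of
convenience, not clinical claims.

## Problem sizes and numerical notes

Desk-scale defaults used by the test suite and the acceptance script:
phantoms of 128–256 px square, 20 training patches of 64 x 64, a
12/24-channel tiny encoder trained 50 epochs, FROC over a 19-point
threshold sweep on a handful of images, and 100 bootstrap replicates.
These sizes make every result reproducible on a single CPU in minutes
while leaving each algorithmic path (multi-scale detection, pruning,
constraint masking, training, tiled inference, matching, bootstrap) fully
exercised.

Degenerate inputs are handled explicitly: empty annotation sets rasterize
to empty masks and proximity maps of zeros; a flat image yields no blobs;
`alpha = 0`, out-of-bounds coordinates, shape mismatches, non-divisible
network inputs, and double normalization raise validation errors rather
than propagating silently. Ties are broken deterministically everywhere
(plateau rule, pruning order, operating-point rule, ROC tie convention).

## Known limitations

The `h_thr` constraint degenerates at its own default (see above) — users
exploring `h_thr < 0.25` get the full constraint, and the flag is exposed.
Blob scale estimates from the `sigma_n/(Delta sigma)` normalization peak
below the object's true width (the test suite pins the exact discrete
argmax with a closed-form oracle), so `sigma` should be read as a scale
index, not a radius estimate. The tiny encoder underfits textures a large
pretrained backbone would capture. Greedy FROC matching can differ from
the optimal assignment in rare crowded scenes; the audit quantifies this
rather than hiding it. DICOM support covers uncompressed little-endian
transfer syntaxes only.
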