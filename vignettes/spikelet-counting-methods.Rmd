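---
title: "Counting spikelets from point annotations: models, targets and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting spikelets from point annotations: models, targets and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeletr)
```

## The problem

The number of spikelets per spike is a standard productivity trait in
wheat phenotyping, and counting them by eye is slow and subjective.
Full training annotation — pixel masks or tight bounding boxes around
every spikelet — is the main cost bottleneck for learned counters.
`spikeletr` implements a counting pipeline built on the cheapest
annotation there is: a single expert click per spikelet center. The
click coordinates are expanded automatically into dense training
targets, a segmentation network is trained on those targets, and its
per-pixel predictions are decoded back into center points that can be
counted and spatially scored.

Every physical parameter of the method is specified in millimetres and
converted through an explicit pixels-per-millimetre calibration
(`scale_calibration()`), because a raster radius is meaningless across
images shot at different distances. The calibration is supplied per
dataset (or per image); the package never tries to infer it from image
content.

One coordinate convention is used everywhere: `x` indexes columns, `y`
indexes rows, the origin is the top-left pixel, coordinates are 0-based
and pixel centers sit at integer coordinates. Rasterization,
augmentation, decoding and matching all share it, which is what makes
the round-trip invariants in the test suite exact.

## From clicks to training targets

Three target constructions are supported, mirroring the three ways a
point annotation is commonly consumed:

* **Binary disc masks** (`make_binary_mask()`): a filled disc of radius
  `radius_mm` (default 2 mm) around each click; overlaps merge by
  union. A pixel is foreground iff its center lies within the radius —
  deliberately no antialiasing, so a brute-force per-pixel distance
  scan reproduces the raster exactly and serves as the test oracle.
* **Gaussian density maps** (`make_gaussian_mask()`): an isotropic
  Gaussian kernel per click. The motivation is that expert clicks are
  themselves noisy around the true center, with an approximately radial
  Gaussian spread, so a density target models the annotation process
  rather than pretending the click is exact. The default
  `sigma_mm = 1` puts ~95% of each kernel's mass inside the 2 mm disc
  radius, keeping the two schemes spatially comparable. Kernels are
  evaluated within ±4σ (the truncated tail is < 1e-4 of the mass);
  normalized maps sum to 1 so they are probability distributions over
  pixels.
* **Square box labels** (`make_box_labels()` /
  `export_yolo_labels()`): a fixed-size square (default 6 × 6 mm) per
  click, exported in normalized YOLO text format so an external box
  detector can be trained on the same annotations. The detector itself
  is out of scope here; `boxes_to_centers()` brings its output back
  into the shared evaluation.

Degenerate cases are handled rather than refused: a disc radius that
covers no pixel still marks the nearest pixel (with a warning), and a
normalized density map of an image with no annotations degrades to a
flagged uniform map so background-only images can participate in
training.

## The segmentation network

The package trains a compact fully-convolutional encoder–decoder
implemented directly in R: two 3×3 convolution blocks, one 2×2
max-pooling level, two more convolution blocks, nearest-neighbour
upsampling with a skip concatenation, a fusion convolution and a 1×1
prediction head. Convolutions are evaluated as im2col patch-matrix
products so the arithmetic runs through BLAS; gradients are
hand-derived (and verified against finite differences in the test
suite) and parameters are updated with Adam. `encoder_name` selects a
width preset — `micro` (8/16 channels), `small` (16/32), `base`
(24/48).

This is intentionally a desk-scale network. It is sized so that the
full pipeline — including training — runs in minutes on one CPU core,
which is what makes end-to-end testing of the *methodology* practical.
The pipeline contracts (targets in, per-pixel maps out, decoding and
evaluation downstream) are the same ones a large pretrained
encoder–decoder would satisfy, and nothing in the decoding or
evaluation layers depends on the network's size.

Two loss contracts connect targets to predictions:

* binary scheme: per-pixel binary cross-entropy on logits
  (`loss_bce()`), with the prediction read out through a sigmoid;
* gaussian scheme: Kullback–Leibler divergence `KL(target ‖ pred)`
  (`loss_kldiv()`), with the prediction normalized by a log-softmax
  over the flattened raster so it is a genuine distribution and the
  divergence is well-defined. The gradient of this pairing with
  respect to the logits is the clean `softmax − target`.

The prediction head's bias is initialized to −2, a low-foreground
prior (~12% after the sigmoid). An untrained network then predicts
"background everywhere" instead of hovering at probability 0.5, where
thresholding amplifies arbitrary texture into spurious detections.
This is the standard prior-bias initialization for class-imbalanced
dense prediction; for the softmax-normalized density head a constant
bias cancels, so it has no effect there.

## Augmentation

`augmentation_spec()` holds the training recipe: resize to a fixed
geometry (default 512 × 224, height × width), horizontal flip
(p = 0.5), vertical flip (p = 0.277), rotation within ±30° (p = 0.735),
Gaussian blur with kernel 1–3 (p = 0.25), Gaussian pixel noise
(p = 0.15), brightness/contrast jitter (p = 0.5), RGB channel shifts of
±15 levels (p = 0.5), color jitter of brightness, contrast, saturation
and hue by 0.2 (p = 0.703) and grayscale conversion (p = 0.1).
Geometric transforms are applied identically to the image and the
target raster and consistently to the annotation points (points
rotated out of the frame are dropped, matching the truncated raster);
photometric transforms touch the image only. Binary targets are
resampled nearest-neighbour to stay crisp, density targets bilinearly
and renormalized. Rotation fills exposed borders with zeros on both
image and target — a reflected border would paint phantom spikelets
into the image with no corresponding target, which is worse than a
dark wedge.

All stochastic decisions draw from R's RNG, so seeding the training
run (`train_config(seed = )`) makes splits, augmentation draws and
weight initialization jointly reproducible; the test suite asserts
bit-identical training histories under a repeated seed.

## Decoding predictions into centers

* Binary maps: threshold at `binary_threshold` (default 0.5), label
  foreground regions with 8-connectivity (8 rather than 4 so diagonal
  necks do not split a region), drop regions below
  `min_region_area_px` (default 0), and return each region's centroid.
* Density maps: candidate areas are regions above a floor
  (`gaussian_floor`, default 1e-4 of the global maximum — density maps
  are strictly positive everywhere, so some absolute cut is needed
  before connectivity is meaningful). Within each area, pixels below
  `C` times the area's maximum (default `C` = 0.5) are removed, the
  survivors are re-labeled, and each resulting region contributes its
  maximum pixel as a center. Plateau ties break deterministically to
  the smallest row, then column. The two-stage rule makes "one center
  per local mode" concrete while leaving both `C` and the floor
  tunable.

Predictions are made at the training geometry and bilinearly resampled
back to the original image size before decoding, so extracted centers
live in original pixel coordinates where the millimetre calibration is
valid.

## Evaluation

A predicted center is a true positive if it lies within `radius_mm`
(default 2 mm) of an unmatched annotated center. Because several
predictions can compete for several truths, the package computes a
maximum-cardinality one-to-one matching on the admissible pairs and,
among maximum matchings, the one of minimum total distance — an
unambiguous, order-independent rule that exhaustive enumeration can
verify on small instances (and does, in the tests). A greedy
closest-pair mode is available for comparison. Precision, recall and
F1 follow from pooled TP/FP/FN counts across images (micro-averaging,
the headline number; per-image macro means are reported alongside).
Counting accuracy is summarized as MAE and MAPE of per-image counts;
images with a true count of zero are excluded from MAPE (division by
zero) with a warning, but still count toward MAE.

Zero-denominator conventions: with no predictions and no truths,
precision and recall are 1; with `TP = 0` and any errors present, the
affected metrics are 0; `F1 = 0` when `P + R = 0`.

## The synthetic spike generator

Real spike photographs with expert annotations are not shipped with
the package, so `generate_spike_image()` renders a controllable
stand-in: textured soft-edged ellipses (default 6 × 3 mm) placed at
4 mm steps along a sinusoidally curved rachis, alternating left/right
by a 2.5 mm rank offset, on a noisy blue background at 2 px/mm, with a
golden-green base color and per-blob color jitter. The exact ellipse
centers are returned as the annotation set, and
`jitter_annotations()` can displace them with an isotropic Gaussian
click error to emulate imprecise experts. `generate_dataset()` writes
seeded image/annotation/manifest layouts; everything is a pure
function of (parameters, seed).

What the generator does *not* emulate: awns, glumes and overlapping
organ morphology, specular lighting, shadows, the color-calibration
card, or clutter. Passing the end-to-end tests on this imagery
demonstrates that the pipeline's plumbing — targets, losses,
optimization, decoding, matching, counting — is correct and internally
consistent; it does not certify accuracy on real spike photographs,
which depends on a stronger encoder and real training data.

## Scaled experiment sizes and tuning

The package's own validation experiments (test suite and
`scripts/acceptance.R`) run at deliberately modest sizes chosen to
keep a full CPU run in minutes: 150 synthetic images of 128 × 64 px
with 6–12 spikelets each, a 60/20/20 split, the `micro` encoder, and
10 epochs for the binary scheme / 15 for the gaussian scheme (the
binary run typically saturates validation F1 around epoch 5–7; the
density run fluctuates more, which is why checkpoint selection keeps
the best-validation-F1 epoch rather than the last). On held-out
synthetic test images both schemes reach micro-F1 ≈ 1 and MAE ≈ 0 at
these sizes.

`tune_hyperparameters()` performs seeded random search, or classical
shuffled grid enumeration when every dimension is categorical; the
objective for model tuning is the validation micro-F1 at the 2 mm
radius (`make_training_objective()`, which memoizes repeated
configurations). The tuning demonstration plants an optimal disc
radius: on a synthetic set whose blobs have a 3 mm minor axis, ranks
offset by only 2 mm (so neighbouring spikelets touch, as they do on a
real spike) and clicks jittered by 0.5 mm, a radius of 1.5 mm — the
blob minor radius — is recoverable as the argmax of a coarse grid:
much smaller discs starve the imbalanced segmentation loss at short
training budgets, and much larger discs merge across the ranks into
targets whose decoded centers collapse. The touching ranks matter:
they ensure an undertrained network that merely segments color cannot
score well transiently, so the search's ranking reflects the target
radius itself.

## Numerical choices and limitations

* Disc rasterization is exact by construction (pixel-center rule);
  Gaussian truncation at ±4σ is far below all test tolerances.
* Bilinear resampling uses the half-pixel convention
  (`x_src = (x_dst + 0.5)·w/w₂ − 0.5`), making identity resizes exact.
* The matching weight `M − d` with `M` larger than any achievable
  total distance makes cardinality dominate distance in a single
  maximum-weight matching solve.
* Density masks are serialized as 16-bit grayscale PNG scaled by the
  map maximum (stored in a JSON sidecar); a package-internal 16-bit
  PNG encoder is used because no installed writer emits 16-bit
  grayscale. Reads go through `png::readPNG`.
* Training holds all images of a run at one fixed geometry; images of
  wildly different aspect ratios are simply resized, which distorts
  physical circularity at prediction time. Evaluation is unaffected
  (it happens in original coordinates), but disc targets generated at
  strongly anisotropic resizes would be ellipses; the package
  rasterizes targets at the original geometry and resamples them with
  the image, which keeps image and target consistent.
* The built-in network has no pretrained weights and a small receptive
  field; it is the right tool for the package's reproducible
  experiments, not a competitive encoder for field imagery.
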