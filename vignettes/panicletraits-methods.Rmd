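---
title: "Methods: occlusion-calibrated panicle trait extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occlusion-calibrated panicle trait extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panicletraits)
```

# The measurement problem

Rice yield is largely set by four panicle traits: the number of grains per
panicle, grain length, grain width, and panicle length. Measuring them by
hand requires threshing and shaping the panicle — slow, destructive, and
error-prone. This package measures all four from a single photograph of the
*intact* panicle laid on a uniform board with a red circular calibrator of
known radius.

Three obstacles shape the method:

1. **Occlusion.** Grains in an intact panicle hide one another, so any
   detector undercounts. We quantify the occlusion with a *panicle
   morphology index* (PMI) and divide the raw count by it.
2. **Scale.** Pixel measurements mean nothing without a physical scale; the
   calibrator ties pixels to millimetres ("pel density").
3. **Shape.** A loose panicle's length is not the height of its bounding
   box; we measure it as the longest bottom-to-top path on the panicle's
   skeleton.

# Models and procedures

## PMI and calibrated counting

For a panicle with true grain count $N_\mathrm{actual}$ and detector
forecast $N_\mathrm{forecast}$,

$$\mathrm{PMI} = 1 - \frac{|N_\mathrm{actual} - N_\mathrm{forecast}|}{N_\mathrm{actual}},$$

clamped to $[0, 1]$ (the raw expression would go negative once the forecast
exceeds twice the actual count, but the index is defined on $[0,1]$). A PMI
near 1 means the detector saw nearly every grain; near 0, severe mutual
occlusion. The calibrated count divides the raw detector count by the PMI:

$$N_\mathrm{grain} = \operatorname{round}\!\left(\frac{N_\mathrm{predict}}{\max(\mathrm{PMI},\, \mathrm{floor})}\right),$$

with half-up rounding (grain counts are integers). When the detector only
*misses* grains, $\mathrm{PMI} = N_\mathrm{forecast}/N_\mathrm{actual}$ and
the calibration is algebraically exact — `calibrate_count()` recovers the
true count for every undercount. The divisor floor (default 0.05,
configurable) guards against blow-up as PMI approaches zero; note that it
deliberately caps the correction for forecasts below 5% of the actual
count, so exact recovery of such extreme undercounts requires lowering the
floor below $1/N_\mathrm{actual}$ (our tests use $10^{-3}$ when exercising
actual counts up to 500).

In production the PMI comes from a trained image-regression model; that
model is out of scope here. The package instead offers the ground-truth
definition above (`pmi_from_counts()`), an `external` provider that reads
per-image PMI values produced by any model, and a desk-scale `heuristic`
that estimates the occluded fraction from the detection boxes
($1 - (\sum A_i - A_\cup)/\sum A_i$).

## Detection and screening

Detections are axis-aligned boxes with confidences, in half-open 0-based
pixel coordinates. The package implements IoU, confidence filtering, and
deterministic greedy NMS, plus a classical color-threshold/watershed
baseline detector (`baseline_detect()`) so the pipeline runs without
trained weights; any real detector can be plugged in through CSV or
COCO-style JSON files.

For morphometry, grains are *screened* to keep only un- or slightly
occluded ones: NMS at IoU 0.8 followed by a confidence threshold of 0.7 —
the combination that best recovered grain length in the source study. The
IoU threshold is applied as the NMS threshold during detection
post-processing; at inference time no ground-truth boxes exist, so an
IoU-against-truth reading is not actionable, and an optional
pairwise-overlap filter (`max_pairwise_iou`, off by default) is provided
separately.

## Grain morphometry

Each screened box is cropped (padding 0 by default; 2 px optional),
thresholded (Otsu on brightness, or a fixed RGB window), and particle
filtering keeps the largest connected component — the grain's main body.
Its minimum-area rotated bounding rectangle, found by rotating calipers
over the convex hull of the *pixel corners*, gives length (long side) and
width (short side). The corner (unit-square) convention makes an
axis-aligned $w \times h$ block measure exactly $(w, h)$; its cost is a
systematic overestimate of up to ~1 px on rotated shapes, which is why
width (the short axis) carries the larger relative error. Multiplying by
the pel density yields millimetres. Panicle-level values are arithmetic
means over measured grains; the mean aspect ratio is the mean of per-grain
ratios, not the ratio of means (the two differ; we report the former).

## Panicle length

The panicle is segmented by thresholding the HSV saturation channel (the
board is gray; the panicle is colored), small components — noise and the
calibrator — are removed, holes are filled, the largest component is kept,
and the mask is thinned to a 1-pixel skeleton. Endpoints are skeleton
pixels with exactly one 8-neighbor. The *bottom* endpoint starts the
search; the up-to-20 endpoints nearest the image top are candidates
("top" read as minimum row — the image is captured panicle-upright); A*
(unit cost per move, Chebyshev heuristic — admissible, so paths are exactly
shortest) finds the shortest path to each, and the candidate path with the
most pixels is the main path. Its pixel count times the pel density is the
panicle length.

Two conversion conventions are provided: `pixel_count` (default; the
quantity the search optimizes) and `euclidean_steps`
($1 + \sum$ step lengths, counting diagonal moves as $\sqrt 2$), because a
pixel count systematically understates diagonal segments by up to
$\sqrt2 - 1$ per step. Both agree on straight vertical paths.

### Thinning

`skeletonize()` uses Zhang–Suen conditions with one deliberate change:
candidate pixels are found in parallel but deleted *sequentially*, each
deletion re-validated against the updated image. Purely parallel
Zhang–Suen deletes both rows of a 2-pixel-wide structure simultaneously —
a 2×2 block, and ultimately a filled disk, vanishes entirely, destroying
topology. The sequential re-check cannot delete a component's last pixels,
so component counts are preserved (a property the tests assert), at the
cost of a scan-order dependence that is deterministic and harmless.

## Evaluation metrics

MAPE, RMSE, MAE, $R^2$ and accuracy compare forecast against actual trait
series. Two conventions required a decision:

* $R^2$ centers on the **mean of the actual values** (the usual total sum
  of squares).
* Accuracy is $(1 - \mathrm{MAE}/\overline{N_\mathrm{actual}}) \times 100$
  with the **mean of actuals** in the denominator — an MAE-to-single-value
  ratio is undefined for a series. The per-item alternative
  ($100 - \mathrm{MAPE}$) is exposed as `accuracy_mape_complement()`.

Detector quality uses single-class mAP at IoU 0.5 with all-points
interpolation of the precision–recall curve.

# The synthetic study conditions

Every stage is verified against a ground-truthed scene generator
(`generate_scene()`): a gray board, a red calibrator disk, a curved stem
with short side branches, and elliptical grains with anti-aliased edges.
Scenes are deterministic given a seed, and batch runs give each scene an
independent substream so scene *i* is reproducible regardless of batch
size.

The defaults emulate the acquisition protocol at desk scale. Smartphone
captures of the source protocol are ~3000×4000 px with a 25 mm-radius
calibrator, i.e. ~0.08–0.125 mm/px, so grains (9.0 × 3.0 mm, sd 0.5/0.2)
span ~70 × 24 px. The default grain scene is therefore 1000×1400 px with a
200 px calibrator (0.125 mm/px). Two presets adapt the geometry:

* `panicle_scene_spec()` — a grain-free branched stem at 0.625 mm/px where
  the whole stem fits in frame. The coarser scale keeps the branched stem
  the *largest* colored component, which is what the mask-cleaning step
  relies on to discard the calibrator; in real photographs that ordering is
  guaranteed by the hundreds of grains a panicle carries.
* `pipeline_scene_spec()` — a connected panicle (150 grains anchored on the
  branch network) on which every stage of `analyze_panicles()` runs.

The simulated detector (`simulate_detections()`) misses each grain with
probability $\alpha \cdot o$, where $o$ is the grain's maximum box IoU
with any other grain — linear in occlusion for analyzability (a logistic
variant can be substituted via the error-model contract), with Gaussian
box jitter and an occlusion-dependent confidence model.

What the generator does *not* emulate: awns, pedicels, shadows, specular
highlights, perspective and lens distortion, touching-but-not-overlapping
grain boundaries, field backgrounds, or detector biases beyond the linear
miss model. Passing tests therefore demonstrate the *algorithms* are
correct and internally consistent at realistic geometry — not that
field-image accuracy will match; that depends on the plugged-in detector
and PMI model.

# Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)`; boxes half-open `[min, max)`, so
  width is `x_max - x_min` with no ±1 bookkeeping.
* Calibrator radius is the equal-area-circle radius
  $\sqrt{A/\pi}$ — robust to ragged red-classification edges; red is
  hue ≤ 10° or ≥ 350°, saturation ≥ 0.4, value ≥ 0.2, all configurable
  (the color rule is a package decision). Multiple red components within
  20% of the largest's area raise an "ambiguous calibrator" error rather
  than guessing.
* Mask cleaning's minimum area defaults to 100 px² at 3000×4000 scale,
  scaled by image area with a 16 px² floor.
* NMS, A* and the main-path search have documented deterministic
  tie-breaks (confidence/coordinates; neighbor scan order N, NE, E, SE, S,
  SW, W, NW; first candidate in sorted order).
* Empty cases are contracts, not crashes: an empty detection set is valid
  almost everywhere, `pmi_heuristic()` warns and returns 1, unreachable A*
  goals return an explicit unreachable result, and per-image pipeline
  failures null the affected fields with a reason string.

The stem-skeleton ground truth records the *Chebyshev* arc length of the
centerline — the pixel count of an ideal 8-connected digital curve — since
counting all rounded sample pixels would double-count staircase pixels and
overstate the target by ~15% on curved stems.

# Problem sizes

The test suite and acceptance script run entirely on generated scenes:
counting studies use 40–50 placement-only scenes per occlusion level
(0.2/0.4/0.6); morphometry uses 8–20 rendered 1000×1400 scenes with 25
grains; panicle length uses 8–20 rendered 700×600 stems; oracle
comparisons use 100 random skeletons (A* vs BFS) and 50 random blobs
(rotating calipers vs a 0.1° angle sweep). These sizes give stable means
while keeping a full run in minutes on one CPU.

# Known limitations

* The unit-square min-rect convention biases rotated widths high by up to
  ~1 px; at 0.125 mm/px that is ~4% of a 3 mm grain width. Halving the
  pixel size halves the bias, so measured mm values shift slightly with
  resolution (within the tested tolerance bands).
* Pixel-count panicle length understates strongly diagonal stems; use
  `euclidean_steps` for slanted captures.
* The baseline detector cannot separate heavily clustered grains
  (watershed splitting helps only moderate merges); it exists to make the
  pipeline self-contained, not to replace a trained detector.
* Grain chalkiness, thousand-grain weight, branch counts and panicle
  architecture typing are out of scope.
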