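---
title: "Flood-fill background extraction and detector dataset preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flood-fill background extraction and detector dataset preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherryfill)
```

## The problem

Fruit-quality grading by object detection is sensitive to the photographic
background: lighting, season and surroundings vary between acquisition
sessions, and a detector trained on raw photographs spends much of its
capacity learning to ignore them. A simple and effective preprocessing step
is to remove the background entirely before training: grow a background
region inward from the image border and paint it white, leaving only the
fruit. `cherryfill` implements that extraction step together with
everything else needed to turn a folder of annotated photographs into a
detector-ready dataset, and to score a detector's output afterwards.

## The extraction model

The background marker is an *edge-seeded, floating-range flood fill*. Every
border pixel is marked as background unconditionally. Then, repeatedly, any
pixel whose color distance to an already-marked **neighbor** is strictly
below a threshold `max_distance` is marked too, until nothing more can be
added. Marked pixels are filled with white; unmarked pixels — the object —
are left bit-identical.

Formally, the mask returned by `compute_background_mask()` is the least
fixpoint of the two rules (border seeding, neighbor propagation). A least
fixpoint is independent of traversal order, so the breadth-first
implementation is a detail, not a semantic choice; the test suite checks it
pixel-for-pixel against a naive synchronous-sweep fixpoint oracle on
hundreds of random images.

Key semantic decisions, each of which was genuinely open:

* **Floating vs. fixed range.** The distance is measured between a
  candidate and the neighbor that reaches it, not between the candidate
  and the original seed. Floating range is what makes the fill track
  smooth background gradients; it is the default. A fixed-range variant
  (distance to the border seed a region grew from) is available via
  `flood_params(range = "fixed")` for comparison.
* **Strict inequality.** A pixel joins when its distance is strictly
  *less than* `max_distance`. A consequence worth knowing:
  `max_distance = 0` marks only the border itself, and two regions at a
  color distance exactly equal to the threshold do not merge.
* **Metric.** Distances are Euclidean over the three raw RGB channels by
  default. A Chebyshev (per-channel maximum) metric is provided because
  per-channel bounds are the convention in some widely used flood-fill
  implementations. No color-space conversion is applied.
* **Connectivity.** 4-connectivity by default — the more conservative
  choice, since diagonal propagation can leak background through
  single-pixel corridors; 8-connectivity is selectable. The mask under 4
  is always a subset of the mask under 8 at equal threshold (tested).

`max_distance` has no universal default: it depends on how smooth the
background is and how strongly the object contrasts with it. It is
therefore a required argument everywhere, including the CLI. For the
synthetic scenes shipped with the package, 50 (half the guaranteed
foreground/background separation) is a comfortable choice; the worked
examples use it throughout.

## Augmentation geometry

Each annotated source image yields exactly five variants: identity, three
counter-clockwise right-angle rotations (90°, 180°, 270°) and a horizontal
flip. Five variants per source is what turns 400 annotated photographs
into a 2000-image corpus. Two conventions had to be fixed: the rotation
direction (counter-clockwise is canonical here; the augmented *set* is the
same either way, since 90° clockwise equals 270° counter-clockwise) and
the flip axis (horizontal; adding a vertical flip would change the
five-variant count).

All five transforms are pixel permutations, so boxes transform exactly: a
box `[x0,x1) x [y0,y1)` on a `W x H` image maps under the 90° CCW rotation
`(x,y) -> (y, W-x)` to `[y0,y1) x [W-x1, W-x0)`, and under the flip to
`[W-x1, W-x0) x [y0,y1)`. The tests verify the formulas against a
mask-rasterization oracle (rasterize the box, transform the raster, take
the tight box) and check the crop-commutation property: cropping the
transformed image to the transformed box equals transforming the crop.

Because the transforms permute pixels and the flood fill is invariant
under border-preserving, adjacency-preserving permutations,
augment-then-extract and extract-then-augment produce identical pixels.
The pipeline defaults to augmenting first (matching how such corpora are
usually constructed) and exposes `order = "extract_first"`, with a test
asserting the commutation.

## Annotation formats

Annotations enter as labelimg-dialect Pascal VOC XML, which uses 1-based
*inclusive* pixel coordinates; internally everything is 0-based,
*half-open* (`x0 = xmin - 1`, `x1 = xmax`), which makes areas and
transforms exact integer arithmetic. YOLO labels are normalized center
format, written at 6 decimal places, which bounds the round-trip error at
half a pixel for images up to ~2000 px. An image with no objects gets an
empty label file, per YOLO convention. The dataset descriptor
(`dataset.yaml`) follows the YOLOv5 dialect so a real detector can consume
the output unchanged.

One deliberate strictness: VOC objects with `xmin >= xmax` (or the y
analogue) are rejected as invalid rather than silently fixed.

## Splitting

`split_dataset()` is grouped and stratified: all five variants of one
source stay in the same partition (otherwise near-copies of training
images leak into the test set), and the 4:1 train/test ratio is enforced
within every grade. With 100 sources per grade this gives exactly 1600
train and 400 test images. The split is a seeded random sample per grade,
so it is deterministic given the seed; the seed is recorded in the
manifest.

## Detection metrics

Evaluation follows the standard detection protocol: greedy matching in
descending confidence order (ties broken by input order), each ground
truth usable once, class- and image-gated, IoU threshold 0.5 for the
headline numbers plus the mean over thresholds 0.50–0.95 in steps of
0.05. Average precision integrates the all-point precision envelope (at
each recall, the maximum precision at any greater-or-equal recall); the
101-point grid used by some detector codebases is available via
`interpolation = "101_point"` and differs by well under a percent at
realistic curve densities (tested). Edge conventions are explicit:
with no detections, precision is vacuously 1 and recall is 0 unless there
was nothing to find; classes detected but absent from all ground truth
count as false positives for precision and are excluded from the AP
macro-average.

## What the synthetic generator emulates — and what it does not

The real corpus this pipeline was designed around is not publicly
available, so the package ships a generator of cherry-like scenes:
an ellipse (the fruit) with a stem and grade-dependent defect spots on a
smoothly varying background. The four grades differ in peel color (bright
red darkening toward grade 4) and spot count (0 to 4), standing in for the
external quality indicators used when grading real fruit.

The generator is built for *provable* extraction correctness rather than
realism: the palette guarantees a minimum color distance
(`separation_margin`, default 100) between any foreground pixel and any
adjacent background pixel, while adjacent background pixels differ by far
less — a gentle linear ramp (default peak-to-peak 20) plus **uniform**
per-channel noise of half-width `noise` (default 2). Uniform rather than
Gaussian noise is deliberate: a hard bound on the adjacent-background step
is exactly what makes flood-fill recovery exact for any threshold between
that step and the margin, so fixture fidelity is a theorem checked by
test, not a statistical hope. Scenes keep a two-pixel background margin
at the border so the background stays border-connected.

Consequently, passing tests demonstrate algorithmic correctness — the
fixpoint semantics, the geometry, the bookkeeping — on scenes where the
right answer is known exactly. They do not demonstrate that any particular
threshold works on real photographs, where shadows, specular highlights
and fruit-colored background objects violate the separation guarantee.
Threshold selection on real data remains the user's judgment call, which
is why `max_distance` has no default.

## Problem sizes and numerical choices

The test suite and the acceptance script use 96×96-pixel scenes, 100
sources per grade (400 sources, 2000 prepared images) for the count
contracts, 200 random ≤16×16 images for the flood-fill oracle comparison,
and 100 random scenes for the fidelity checks — sizes chosen so the whole
suite runs in well under a minute of compute per module on a single CPU
while still exercising every code path. Color distances are computed in
double precision from integer channel values; the only rounding anywhere
is the 6-decimal YOLO serialization (bounded by the half-pixel round-trip
test) and PNG's lossless 8-bit quantization.

## Known limitations

* The flood fill is BFS-based; a scanline variant would be faster on very
  large images but is not needed at these scales.
* No morphological post-cleaning is applied to the mask; a speckled
  background that defeats the threshold stays speckled.
* Boxes are not re-tightened after extraction. Extraction only whitens
  background, so boxes remain valid supersets of the object; on real data
  with imperfect masks they may become slightly loose.
* Synthetic grade parameters are stand-ins, not calibrated to real
  cherries; internal quality indices (sugar–acid ratio, pH, vitamin
  content) are out of scope entirely.
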