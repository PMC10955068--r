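---
title: "From detections to burrow counts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From detections to burrow counts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volecount)
```

`volecount` turns scored bounding boxes from an external object detector
into burrow counts for aerial rodent surveys, and evaluates every step of
that transformation. This vignette explains the statistical machinery, the
parameters that matter, and the design decisions taken where conventions
genuinely diverge.

## Geometry and matching

All boxes are axis-aligned rectangles in continuous pixel coordinates,
half-open (`[x_min, x_max) × [y_min, y_max)`), origin at the image top-left.
The half-open convention means adjacent tiles partition a scene with no
shared boundary pixel; intersections are computed analytically, never on a
raster. Zero-area boxes are rejected as invalid geometry rather than
silently scored 0.

Two overlap measures drive everything:

- **IoU** (intersection over union) decides whether a detection and an
  annotated burrow are the same object. It penalises both under- and
  over-coverage, which is what you want from a localisation criterion.
- **IoS** (intersection over the *smaller* box) decides whether two
  detections are duplicates. A truncated re-detection of a burrow — the
  typical artefact of tiled inference — is nearly contained in its full
  counterpart, so IoS ≈ 1 even though IoU may be far below any usable
  threshold; conversely two adjacent distinct burrows keep IoS small. We
  define the denominator as `min(area(A), area(B))` so the measure is
  symmetric and duplicate suppression is order-independent.

Matching is the de-facto standard greedy scheme: within each image,
detections at or above the confidence cut are processed in descending
confidence, and each claims the not-yet-matched ground truth with the
highest IoU provided it reaches the IoU threshold. Unmatched detections are
FP, unmatched truths FN. The matcher is deterministic — IoU ties resolve to
the lower ground-truth row, confidence ties to the earlier detection row.
Greedy matching can in principle differ from the optimal assignment, but
only on constructed tie cases; the test suite verifies agreement with an
exhaustive matcher whenever detections overlap at most one truth each. A
useful structural property: the match at cut *c* is exactly the prefix of
the full confidence-descending sweep, so PR curves and MR–FPPI curves come
from a single pass.

## Classification vs. count-regression metrics

Precision, recall and F1 summarise the matcher's counts; AP integrates the
all-point interpolated precision envelope over recall at thresholds equal to
the distinct confidence values (so AP is invariant under duplicating every
image — it is count-weighted, not image-averaged). With a single class, mAP
equals AP. Degenerate denominators are flagged (`NA` plus a
`precision_defined` field), never silently zeroed or thrown.

Counting is a different loss. A survey tolerates a bounded number of false
alarms per image regardless of burrow density, which is what FPPI = FP/N
expresses; MR = FN/GT = 1 − recall is its partner. Sweeping the confidence
threshold traces the MR–FPPI step curve, summarised by **LAMR**: MR read at
nine FPPI references `10^(-2 + 0.25k)`, k = 0..8. Reading is step-wise (the
MR of the largest achieved FPPI at or below the reference); references
beyond the curve's end take the minimum MR achieved, and references below
the curve's start take the first point's MR. The nine values are averaged
arithmetically by default; `log_average = TRUE` gives the geometric-mean
convention used in pedestrian-detection benchmarks. The two differ
numerically, so the switch is explicit and defaults to the plain average.

**MAPE** scores the deployed counter: `mean(|ES_i − GT_i| / GT_i)` over
images with at least one true burrow (images with `GT_i = 0` are excluded —
the ratio is undefined — and their number is reported). `ES_i` is
deliberately the *raw* count of detections above the cut, with no matching:
in deployment there is no ground truth to match against, and a false alarm
genuinely compensates a miss in the total.

## Threshold calibration

Two knobs define the operating point.

- **IoU threshold.** LAMR as a function of the IoU grid
  (default 0.05, 0.20, 0.35, 0.50, 0.65, 0.80, 0.90) is flat while the
  threshold is loose and rises sharply once it exceeds what the detector's
  localisation accuracy supports. "The knee" is operationalised as the
  largest grid value whose LAMR is within δ of the grid minimum, δ = 0.02
  absolute by default and exposed in `sweep_iou()`. A visual-inflection
  rule needs a formal surrogate to be testable; this one picks the tightest
  threshold that costs essentially nothing in miss rate.
- **Confidence threshold.** `sweep_confidence()` evaluates every cut on a
  grid (step 0.01 by default, giving two-decimal thresholds) and reports
  both the F1 argmax and the MAPE argmin, ties broken toward the higher
  threshold (fewer false positives at equal metric). The optima coincide
  only when false-positive confidence mass is well separated from the
  true-positive distribution; with overlapping distributions the
  counting-optimal cut drifts away from the F1 one, which is why both are
  reported and the regression view is preferred for surveys.

## Tiled inference and merging

Survey frames are large (8192×5460 px at full resolution); detectors run on
tiles (1708×1160 in the motivating design, a 5×5 grid). `plan_grid()` spaces
tile origins evenly with stride `floor((scene − tile)/(n − 1))` and clamps
the final row/column to the scene border, so adjacent tiles share an overlap
band (87 px and 85 px for the numbers above). A burrow sitting on a seam is
detected in two or more tiles; after mapping detections to scene
coordinates, `ios_nms()` removes duplicates greedily in descending
confidence, suppressing any box whose IoS with an already-kept box exceeds
the threshold (default 0.5).

Two design details matter more than they look:

- **Overlap width** should be at least 2–3× the typical box size. Then any
  box crossing a seam lies entirely inside the overlap band, hence entirely
  inside at least one tile — so a complete copy of every burrow exists, and
  every fragment has IoS 1 against it. Under an exact detector the merged
  count then equals the scene count for *any* valid grid (the tile-invariance
  property in the test suite). Much wider overlaps only add computation.
- **Confidence ties.** Equal-confidence duplicates are real: an exact or
  quantised detector emits identical scores for re-detections. Ties resolve
  toward the larger box (then input order). If instead the first-seen
  fragment wins, a kept sliver can fail to suppress an orthogonally clipped
  fragment of the same burrow and the count inflates; preferring the most
  complete box removes the failure mode while staying deterministic.

Confidence filtering runs before suppression — the result is identical
(suppression never resurrects a box) and the quadratic NMS loop sees fewer
boxes.

## Survey design helpers

`gsd_cm_per_px()` is the standard pinhole relation
`100 · h · (s/w) / f` (h in m, sensor width s in mm, image width w in px,
focal length f in mm). Defaults describe a 45-megapixel full-frame camera
with a 35 mm lens (s = 36 mm, w = 8192 px); the sensor width is inferred
from the camera class rather than a datasheet, and is validated in the test
suite by reproducing the expected one-decimal resolution values across the
10–100 m height range. GSD is linear in height.

`resolution_eval()` scores manual visual interpretation at a candidate
height from three primitive counts: the field count GT, the image-based
count IT, and TP, the interpreted burrows that are real. Precision is
defined as TP/IT and recall as TP/GT — the convention under which every row
of such scoreboards is internally consistent — with FP = IT − TP and
FN = GT − TP derived for display. Displayed values are rounded half-up to
two decimals (banker's rounding would disagree with reported tables on
exact .xx5 cells); full precision is retained in `*_exact` fields.

`count_validation()` implements the regional validation trio. Its R²
convention normalises by the variance of the *model* series:
`R² = 1 − Σ(x_i − y_i)² / Σ(x_i − x̄)²`. That is the form used in the
survey-validation literature this package follows; it differs numerically
from the textbook form normalised by the reference variance, which is
available via `r2_reference = TRUE`. R² can be negative, and a constant
model series leaves it undefined (flagged, not thrown). Regional accuracy is
`(1 − |N_gt − N_est|/N_gt) · 100`, symmetric in over- and under-counting.

## The synthetic survey generator

The generator exists so that every pipeline stage has a testable oracle
without field data. It emulates, with everything seeded and reproducible:

- **Scenes**: 1708×1160 px sub-images by default, with a Poisson number of
  burrows per scene (mean 3.6, matching roughly 3.6 annotated burrows per
  valid sub-image in the motivating survey, i.e. tens of burrows per
  600 m² at 0.4 cm/px). Box sides are Gaussian around 40 px (CV 0.15) —
  a burrow entrance plus its trampled vole trails at that resolution — with
  a `label_margin` factor emulating the practice of labelling out to the
  trails. Placement is uniform by default; a parent–offspring clustered
  mode reflects the aggregated distribution of real burrow systems. A
  minimum centre distance (default one mean box side) keeps distinct
  burrows from coinciding.
- **The detector**: each truth is found with probability `p_detect`
  (default 0.9), corners jittered with sd 2 px, confidence drawn from
  Beta(8, 2); clutter false positives (dung and shadows) arrive as a
  Poisson per image (mean 2), sized like burrows, with Beta(4, 4)
  confidences. The false-positive upper tail deliberately overlaps the
  true-positive distribution: that is the regime in which the F1-optimal
  and MAPE-optimal cuts separate, and it is what makes the calibration
  machinery worth testing.
- **Tiling**: `tile_scene()` clips boxes to every tile they intersect,
  manufacturing the seam duplicates the merger must collapse. Truth
  fragments showing less than 25% of their area in a tile are dropped from
  that tile's truth — an annotator would not label a sliver; detection
  fragments are kept at any positive area.

Master seeds derive per-stage sub-streams (`derive_seed()`, a Lehmer step
modulo 2³¹ − 1), so a stage can be re-run independently yet reproducibly,
and derived seeds stay within R's 32-bit integer range.

What the generator does *not* emulate: correlated misses in dense clusters,
confidence–localisation correlation, vegetation-dependent false-positive
rates, and anything about pixels. Passing tests therefore demonstrate the
*metrology* — that matching, curves, calibration and merging compute what
they claim on data with known structure — not that any particular detector
will reach a given accuracy in the field.

## Problem sizes and numerical choices

The property suites run on deliberately modest sizes chosen as the smallest
that exercise the mathematics: 50-image surveys for threshold calibration
(≈180 burrows), 200-image surveys across five seeds for detector parameter
recovery (binomial/Poisson 3σ tolerances), 100–200 random box pairs against
the rasterization oracle, and scenes of 12–18 burrows for tile-invariance.
Oracle comparisons are exact to 1e-12 where the computation is closed-form
(LAMR's nine-point loop, the exhaustive threshold sweep) and 1e-6 against
the unit-cell rasterization. Degenerate inputs follow one rule everywhere:
impossible geometry and impossible requests error; undefined statistics are
flagged `NA` with a `*_defined` companion.

## Limitations

Single class only; axis-aligned boxes only (no rotated boxes, masks or
geographic coordinates); no orthophoto stitching — regional counting starts
from detections already expressed in a common frame; greedy (not optimal)
matching, as in the standard benchmarks; and the LAMR averaging convention
must be chosen by the user when comparing against published values, since
both conventions are in circulation.
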