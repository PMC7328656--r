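---
title: "Methods: annotation regimes, metrics, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation regimes, metrics, and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomask)
```

## The problem

Digitized herbarium sheets carry detailed phenological information: the
counts and sizes of flower buds, open flowers, immature fruits, and mature
fruits on a specimen quantify its phenophase far more precisely than a
presence/absence flag. Scoring these organs by hand takes roughly a minute
per structure, so automating their detection, segmentation, counting and
measurement is what makes collection-scale phenological studies feasible.

phenomask implements the surrounding method for such a system: the three
annotation regimes used to train instance-segmentation models on herbarium
sheets, a pluggable detector contract, the complete evaluation suite, and a
synthetic sheet generator that makes every metric testable end to end with
exact ground truth and analytically known expectations. Training a deep
detector is deliberately out of scope; any detector that can emit
COCO-style scored masks plugs into the evaluation through
`read_predictions()`.

## Coordinate conventions

All geometry uses the COCO pixel convention: origin at the top-left corner,
x rightward, y downward, 0-based indices. Bounding boxes are half-open,
`[x, x + w) × [y, y + h)`, so `w` and `h` are pixel counts. A pixel belongs
to a polygon when its center falls inside it (even-odd rule); rasterization
is implemented as an exact scanline fill at pixel centers. This makes
"rasterize, then re-extract the bounding box" idempotent, which the tests
verify on random polygons. Masks are stored as polygons in files and
rasterized lazily for metric computation; raster-only masks (Otsu partial
masks, jittered predictions) are written as exact rectangle decompositions
of their pixel runs so file round-trips never change a mask's area.

## The three annotation regimes

**Point masks.** Organ counting protocols place one colored marker per
visible structure. `make_point_mask()` turns each marker into a 3 × 3 pixel
square centered on it. At image borders the square is clipped — a corner
marker yields a 2 × 2 mask — so mask areas are always in {4, 6, 9}.

**Partial masks.** `make_partial_mask()` thresholds the luminance
(0.299 R + 0.587 G + 0.114 B, a standard and reproducible choice) of the
100 × 100-pixel window centered on the marker with Otsu's method, takes as
foreground the threshold class that contains the marker pixel, and keeps
the 8-connected component containing the marker (or the component with the
nearest centroid if none contains it — a guard that cannot trigger under
the current polarity rule but keeps the selection total). The 100-pixel
window corresponds to 0.84 cm at the default calibration: wide enough to
capture buds and flowers whole, narrow enough not to swallow background
around large fruits. An even window size cannot center exactly on a pixel;
the window spans `[x − 50, x + 50)` (left-biased). A window whose histogram
occupies a single gray level is degenerate; the builder then falls back to
the point mask and warns.

The Otsu implementation scores every candidate threshold `t ∈ 0..255`
splitting the histogram into a low class (levels ≤ t) and a high class,
and maximizes the between-class variance

    sigma_b²(t) = w0(t) · w1(t) · (mu0(t) − mu1(t))²

with ties broken toward the smallest `t`. The test suite checks it against
an exhaustive brute-force search on random windows; the implementation is a
vectorized cumulative-moment formulation of the same objective.

**Full masks.** Hand-drawn complete outlines, one polygon per structure,
with only the foreground structure annotated where organs overlap.
`validate_full_masks()` report-checks a sheet for self-intersecting
polygons, zero rasterized area, and exactly duplicated geometry.

## Evaluation metrics

**Matching.** Predictions are processed in decreasing confidence order;
each claims the unclaimed ground-truth instance of highest IoU strictly
above the threshold (default 0.5). The geometric claim is
category-agnostic: a flower mask predicted as a bud still matches its
flower, and the label error is charged later. This is what lets the
confusion matrix register cross-category confusions at all. Tie-breaks are
deterministic (equal scores: lower prediction id first; equal IoU: lower
ground-truth id), so matching is invariant to input order.

**Average precision.** For a category with `N_gt` ground-truth instances,
predictions of that category are ranked by decreasing score and

    AP = (1 / N_gt) · Σ_k P(k) · δ_k,

where `δ_k` is 1 when rank k geometrically matched a ground-truth instance
of the same category and `P(k)` is the precision over the top k ranks.
AP is 1 exactly when all `N_gt` instances are retrieved with no
higher-ranked errors. Size-wise AP partitions ground truth by the maximum
bounding-box side into Small (1–64 px), Medium (65–128 px) and Large
(> 128 px) bins — 0.54 cm and 1.08 cm at the default calibration — and
computes AP within each bin with the four categories pooled; matched
predictions inherit their ground truth's bin, false alarms are binned by
their own box.

**Counting precision.** `CP = 100 · detected / true`, per sheet and per
category, plus the metacategories `buds_flowers` and `fruits` and the
pooled `all`. The defining prose of this ratio is usually stated
true : detected, but its interpretation — above 100% means the automated
count *overestimates* — forces detected / true; we implement that
direction, and the same for measurement precision. Counting uses
predictions at or above a score cutoff (default 0.5) and involves no IoU
matching.

**Confusion / detection probability matrix.** Entry (i, j) is the fraction
of ground-truth instances of category i whose matched prediction carries
category j. Because matching is greedy by score, the matched prediction is
the best-scoring one. Rows need not sum to 1; `1 − sum(row)` is the
misdetection probability.

**Measurement.** The size of an instance is the diagonal of its mask's
bounding box, `sqrt(w² + h²)`, converted to centimeters via the calibration
(default 0.0084 cm/px, i.e. 100 px = 0.84 cm). Note the two size
definitions coexist deliberately: binning uses the maximum box *side*,
measurement the box *diagonal*. A square box at the Large-bin boundary
(side 128 px) therefore measures 1.52 cm while the bin boundary in side
units is 1.08 cm — both numbers are correct and refer to different
quantities. Reported centimeters are rounded half-up to 2 decimals.
`MP = 100 · mean(predicted sizes) / mean(true sizes)` per sheet and
category.

## Image resizing

Sheets are resized so the longest edge is 2048 px. Source material
sometimes states the pair 2048 × 1024, which only fits sheets with exactly
2:1 aspect; we preserve aspect ratio and scale the long edge, since
non-uniform scaling would corrupt every downstream size measurement. The
same single factor is applied to all mask coordinates, so bounding-box
diagonals scale with the image (verified to 1 px in the tests).

## The synthetic test bed

`generate_sheet()` renders procedurally shaped organs on a paper-colored
background with Gaussian pixel noise (sd 0.015):

| category        | shape                | size range (px)          |
|-----------------|----------------------|--------------------------|
| bud             | ellipse              | axes 10–40, elongation < 2 |
| flower          | lobed disc (4–6 petals) | diameter 30–90        |
| immature fruit  | thin curved capsule  | length 60–250, width 6–14 |
| mature fruit    | curved capsule       | length 120–360, width 8–18 |

The default per-sheet counts (13 buds, 17 flowers, 9 immature and 10
mature fruits) are the annotated training material's per-category totals
divided by its 21 sheets, so a default suite has realistic composition, and
the size ranges span all three size bins. Placement is rejection sampling
with margin-separated bounding boxes (8 px), which emulates the
foreground-only annotation rule: each pixel belongs to at most one
instance. Every random draw flows from the recipe seed through a documented
splitting scheme, so fixtures are byte-reproducible.
`generate_fixture_table1()` builds annotation-only fixtures with exactly
the study totals (279/349/196/212 training over 21 sheets, 168/299/110/101
test over 10), allocating instances to sheets at random under the seed.

What the generator does **not** emulate: overlapping and occluded organs,
stems and leaves, glue, labels, handwriting, specimen deterioration, and
the true morphological variability of *Streptanthus* material. Passing
metrics on synthetic sheets therefore demonstrate the correctness of the
measurement machinery, not real-world detector performance.

**Perturbation model.** `perturb_predictions()` corrupts ground truth with
independent per-category miss probabilities, Poisson false alarms,
a row-stochastic label-swap matrix, and mask jitter implemented as
morphological dilation (monotone: a larger radius never shrinks a mask, so
per-instance IoU against the original is non-increasing). Detection scores
are `0.5 + 0.5·Beta(12, 2)` and false-alarm scores `0.5·Beta(2, 12)`, so the
default counting cutoff of 0.5 separates them exactly and the identity
model reproduces every headline metric perfectly (CP = 100%, AP = 1,
identity confusion, MP = 100%) — an exact end-to-end invariant rather than
a statistical one. Under a miss rate `p`, false-alarm rate `λ` per sheet
and swap matrix `S`, the analytic expectations are

    CP ≈ 100 · ((1 − p) + λ / N̄)   and   confusion ≈ (1 − p) · S,

with `N̄` the mean instance count per sheet. The recovery checks use a
score cutoff of 0 so these hold without modelling how much score mass falls
below the counting cutoff, and assert agreement within 3-sigma binomial
bounds at about 1000 instances.

## The baseline detector

`baseline_segment()` exists so the pipeline runs end to end without any
trained model: global Otsu on luminance (darker class = pressed material),
connected components, then a rule table on per-component shape and color —
elongation at least 3 (square root of the principal-axis variance ratio of
the pixel coordinates) makes a fruit, split immature/mature by mean hue
(green = 60–180°); compact components are flowers when purple-hued
(200–330°), buds otherwise. Scores map the rule margin into [0.5, 1].
Because Otsu always splits a histogram, an organ-free sheet would otherwise
yield a giant noise "foreground"; a foreground-fraction guard (default
maximum 0.25) rejects such splits, since sparse herbarium material covers
far less of the sheet while the darker half of paper noise covers ~40%.
Components under 40 px are dropped as noise. These defaults were tuned once
on the synthetic suite and frozen in `baseline_config()`. The rule table is
matched to the synthetic palette and shape classes; on real sheets it is
only a placeholder for a trained detector.

## Numerical choices and degenerate inputs

- Otsu ties break to the smallest threshold; the marker pixel's class is
  foreground (at the boundary the marker level is in the ≤ t class, i.e.
  the darker side).
- Zero-area masks are constructible (a degenerate polygon) but `iou()`
  refuses them; full-mask validation flags them instead.
- Matching with equal scores or equal IoU is resolved by instance id, so
  results never depend on list order.
- `AP` for a category with no ground truth is `NA` (absent), not 0; the
  same for empty size bins, empty confusion rows and sheets with no true
  instances of a category in CP/MP.
- Infeasible packings (more organ area than a sheet can hold at the
  required separation) abort with a diagnostic rather than degrading the
  overlap guarantees.

## Problem sizes used by the test suite

The suite favors exactness over scale: oracle equivalence runs on 100
random windows/suites, identity and jitter properties on 2–3 default
sheets (~50 instances each), parameter recovery on the 21-sheet / 1036
instance training fixture, and the baseline on three 1024 × 768 sheets
with 19 organs each. `scripts/acceptance.R` recomputes the same quantities
from scratch at those sizes.

## Known limitations

- Polygons only in files (no RLE); multi-polygon segmentations are merged
  into raster masks on read.
- The baseline detector cannot separate touching organs (one connected
  component) and knows nothing about real herbarium appearance.
- Mean matched IoU under jitter is guaranteed non-increasing only while the
  matched set is stable; the monotonicity checks therefore match at an IoU
  threshold of 0.2 so heavily dilated thin fruits stay matched across the
  radius grid.
- Aspect-preserving resize means the short edge is generally not 1024 px;
  see the resizing section.
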