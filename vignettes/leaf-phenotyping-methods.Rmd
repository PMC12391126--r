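---
title: "Methods: mask post-processing, leaf tracking and growth-rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask post-processing, leaf tracking and growth-rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaftracker)
```

This vignette documents the models, conventions and numerical choices
behind `leaftracker`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic test bed does and does
not establish about real data.

## Coordinate and raster conventions

All pixel coordinates are 0-based with the origin at the top-left corner,
x rightward and y downward. Pixel `(x, y)` covers the half-open unit
square `[x, x+1) × [y, y+1)`; a pixel belongs to a polygon's raster when
its centre `(x+0.5, y+0.5)` lies inside the polygon (even-odd rule). This
half-open pixel-centre convention makes rasterization idempotent under
the normalized-TXT round trip: an axis-aligned rectangle serialised to
six-decimal normalized coordinates and re-rasterized reproduces its
raster pixel for pixel. Binary masks are integer matrices valued in
{0, 255}; any accumulation (mask merging) is clamped back to 255, so the
merged raster is exactly the set union of instance foregrounds.

Out-of-bounds polygon vertices are clipped to the image rectangle with a
warning rather than rejected, because geometric augmentation (rotation)
legitimately pushes vertices outside the frame.

## Mask refinement

Segmentation networks produce masks with serrated edges and occasional
pinholes; both bias pixel counting. `refine_mask()` processes each
connected component:

1. **Boundary extraction.** The ordered outer contour is traced on the
   binary mask. (On a thresholded mask this coincides with the Canny edge
   set; `canny_edges()` — Sobel gradients, non-maximum suppression,
   double-threshold hysteresis with defaults 50/150 on the 0–255 scale —
   is exposed for gradient-based edge maps on arbitrary rasters.)
2. **Resampling and smoothing.** The contour is resampled uniformly by
   arc length to at most `contour_points` (default 200) points, smoothed
   circularly with a Gaussian kernel of bandwidth `spline_smoothing`
   (default 2 points), then densified with a periodic cubic spline.
3. **Refill and closing.** The smoothed closed curve is rasterized with
   its interior filled *and* its boundary trace drawn (interior-only
   filling would lose roughly half the boundary pixels and shrink a
   40 × 40 px square by ~5 %; with the trace included the area error on
   convex fixtures stays under 2 %). Holes are refilled and one
   morphological closing (dilation then erosion, 3 × 3 elliptical
   element) removes residual pinholes.

An empty mask is returned unchanged; components with fewer than 8
boundary pixels are passed through unsmoothed, since a periodic spline
through so few points is meaningless. Refinement is applied per instance,
*before* merging and statistics, because tracking consumes per-instance
masks; the merged frame raster is a reporting artifact, not a tracking
input.

## Cross-frame label tracing

The first frame of a planted experiment shows `rows × cols` leaves
(default 4 × 4). Instances are sorted by centroid `Cy`, chunked into
`rows` groups of `cols`, each group sorted by `Cx`, and IDs 0–15 are
assigned row-major. Chunked sorting rather than fixed horizontal bands
makes the assignment robust to vertical drift of a whole row; a ±5 px
centroid jitter at 100 px pitch cannot change the result. Any other
instance count in the first frame is an error prompting manual review —
guessing a partial grid silently would poison every downstream ID.

Subsequent frames inherit IDs by mask IoU against each live track's
*most recent* observation (growth makes early masks stale). Matching is
greedy in descending IoU with a strict `> 0.5` threshold; each track
accepts at most one instance per frame. When two candidates both exceed
the threshold against one track, the higher IoU wins and the loser falls
back to its next-best track or opens a new ID beyond the grid range.
Tracks that miss a frame stay live indefinitely: leaves are sometimes
under-segmented for a few frames, and the growth-rate formula spans the
gap using actual elapsed hours. IoU computations visit only the
bounding-box overlap region, so a 100-frame, 16-leaf series tracks in
seconds.

The method assumes approximately stationary, monotonically growing,
non-occluded targets — the regime of a germination tray. It has no
motion model and is not suitable for moving objects.

## Calibration, area and growth rate

With square pixels and a scene of physical width `W_mm` imaged at
`W_px`, one pixel represents `(W_mm / W_px)²` mm² (default 250 mm /
1800 px → 0.0193 mm²/px). Leaf area is that constant times the
foreground count, so areas are linear in mask scale. The 1850 px image
height of the reference setup is assumed to share the same mm/px scale;
non-square pixels would need a second calibration constant.

Growth rate divides the area difference by the elapsed time in hours,
taken from filename timestamps — the pipeline is deliberately agnostic
about the capture cadence (15 and 30 min rigs both occur) and never
assumes a fixed interval. The default window is consecutive frames; any
span in frames or hours can be requested. Because consecutive-frame
rates telescope, summing `rate × Δt` per leaf reconstructs the net area
change exactly (to float precision) — a conservation law the test suite
asserts. Negative rates are genuine outputs of the pipeline (mask noise)
and are retained unless `clamp_negative = TRUE`; box-level summaries
average IDs 0–15 only, using each leaf's observation at or nearest
before the query time.

## Evaluation metrics

Matching is greedy in descending confidence; a prediction claims its
best unmatched ground truth at `IoU ≥ t` (evaluation uses ≥, the
conventional COCO-style inclusive threshold, whereas tracking uses the
strict > of its own rule). Precision, recall and F1 leave undefined
ratios as `NA` rather than coercing to zero — a detector with no
predictions has undefined precision, not perfect or zero precision. AP
integrates the all-point-interpolated precision envelope (monotone
non-increasing hull); the suite checks it against a brute-force
integration oracle on *every* TP/FP pattern of up to six ranked
detections. With one class, mAP50 is identically the AP at 0.50.
`FLOPs = 2HW(C_in K² + 1)C_out` keeps the bias term while
`Params = C_in K² C_out` counts weights only; the asymmetry is
deliberate, matching how these quantities are conventionally reported.

## Validation statistics

The manual-vs-algorithm comparison uses closed-form simple least squares
(slope from centred cross-products, intercept from the means), Pearson
r, `R²` and `adjusted R² = 1 − (1 − R²)(n − 1)/(n − k − 1)` with `k = 1`.
For simple regression with intercept, `r² = R²` to 1e-12 — asserted on
random data against `lm()`. Residual diagnostics report mean, standard
deviation and a Shapiro–Wilk statistic (an omnibus normality test chosen
for its power at the few-hundred-sample sizes typical of validation
subsets; it is skipped above 5000 samples where it is unreliable), plus
QQ coordinates for plotting.

## Dataset construction

The retention filter removes a leading window (frames within
`exclude_before` hours of the first frame, half-open), a trailing window
(within `exclude_after` hours of the last), and an explicitly flagged
subset, as a set union — a frame excluded twice is removed once.

Splitting shuffles with a seed, then takes `round(N·0.7)` and
`round(N·0.2)` items for train and validation with the remainder to
test. Nearest-integer rounding for the first two subsets is the only
convention that yields 1895/541/271 from 2707 (flooring would give
1894), and the remainder rule guarantees the sizes sum to `N`.

Augmentation draws each parameter uniformly from its range: rotation
±45°, hue ±180°, brightness ±90 %, blur up to 5.7 px (Gaussian, with
σ = radius/2 so the effective ~2σ support respects the bound), and
salt-and-pepper noise on up to 8.26 % of pixels (the bound names a
fraction of pixels, so a replacement noise model is the natural
reading). Rotation is applied identically to the image and the polygon
vertices (about the image centre, clockwise on screen); photometric
transforms touch only the image. How many augmented copies to derive per
source image is a user decision — no default multiplicity is claimed.
Split-then-augment is the default order, avoiding augmented siblings of
one source leaking across subsets; the opposite order is available for
users who want to reproduce pipelines that augmented first.

## The synthetic scene generator

`render_scene()` exists so that merging, tracking, calibration and rate
estimation can be tested end-to-end against *exact* ground truth.
Each leaf is an ellipse (aspect 0.8, random orientation) with a bounded
Fourier boundary jitter `m(θ) = 1 + Σ_k (α_k cos kθ + β_k sin kθ)`;
since the enclosed area scales by the analytic factor `mean(m²) =
1 + Σ(α_k² + β_k²)/2`, the semi-axes are corrected so the target pixel
area is hit exactly up to rasterization (the suite requires < 3 %
relative error at ≥ 100 px, and observes well under 1 %). Leaf area
follows `A(t) = f·A_max / (1 + exp(−r·f·(t − t_mid)))` with
`f(c) = exp(−c/60)` damping both asymptote and rate with stressor
concentration — slow early growth, fastest expansion mid-window,
ordered suppression across concentrations.

Defaults (asymptote 1200 mm² per leaf with ±10 % per-leaf spread, rate
0.021 h⁻¹ ± 10 %, midpoint 123 h ± 6 h, window 36–192 h at 15 min,
250 mm scene width) were chosen once to emulate a seedling tray whose
control boxes pass a few hundred mm² mean leaf area on day 2 and
approach 1000 mm² by day 7, while fitting a 50 mm grid pitch without
contact. The generator refuses specs whose asymptotic leaf radius cannot
fit the pitch (guaranteed collision) unless occlusion is explicitly
allowed. The frame schedule is half-open (`start, start+Δ, …, < end`),
which makes a 156 h window at 15 min exactly 624 frames. Instance order
within each frame is shuffled so tracking cannot succeed by input order.

What the generator does **not** emulate: real leaf morphology (lobes,
serration beyond low-order jitter), specular highlights and shadows,
detector failure modes (split/merged instances, hallucinated masks),
camera motion, or occlusion by stems. Consequently, passing the
synthetic end-to-end suite establishes the *computational* correctness
of the pipeline — identity bookkeeping, calibration arithmetic,
conservation properties — but says nothing about the accuracy of any
particular segmentation network on real imagery; that is what the
evaluation-metric and validation-statistics modules are for.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run on deliberately scaled
scenes: a 320 × 320 px frame (80 px pitch) tracks 16 leaves over 72–100
frames in a few seconds, and all acceptance-style checks complete in
well under a minute on one CPU. Closed-form quantities (calibration,
rates, FLOPs, regression) are asserted to 1e-9 or tighter; raster-derived
quantities carry a 2–3 % tolerance reflecting boundary-pixel
quantisation at these leaf sizes (hundreds to a few thousand pixels).
Determinism is part of the contract: every randomised operation takes a
seed, uses it through `withr::with_seed()` without touching the global
RNG state, and CSV/JSON writers fix their floating-point formatting, so
identical seeds produce byte-identical artifacts.

## Known limitations

- Tracking has no re-identification: a leaf lost long enough to shrink
  below the IoU threshold against its own stale mask opens a new ID.
- The grid initialiser requires exactly `rows × cols` first-frame
  instances; partially emerged trays need manual review.
- Calibration assumes square pixels and a fronto-parallel scene; no
  projective correction is attempted, and 3-D leaf curvature makes all
  areas projected areas.
- The ISAT-style reader consumes polygon segmentations only; run-length
  encoded masks are not parsed.
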