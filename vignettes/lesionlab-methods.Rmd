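---
title: "lesionlab: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lesionlab: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionlab)
```

This vignette documents the algorithms implemented in **lesionlab**, the
numerical conventions they follow, and the reasoning behind the main design
decisions. The package is a complete dermoscopic-lesion analysis pipeline:
enhancement, hair removal, splitting and augmentation, watershed segmentation,
radiomic and deep feature extraction, fusion, classification and evaluation.
Everything runs offline against a built-in synthetic image generator.

## 1. Synthetic data as the substrate

Real dermoscopy archives are large, licensed and unavailable at check time, so
the package ships a generator (`synthetic_spec()`, `generate_dataset()`)
rather than data. Lesions are star-shaped regions — an ellipse whose boundary
radius is perturbed by low-order Fourier terms — which guarantees a simply
connected ground-truth mask. Per-class signatures vary lesion color and
texture grain; nuisance factors (hair strokes, smooth illumination ramps) are
optional knobs. Every image is a pure function of `(spec, index, seed)`:
randomness is routed through a wrapper that seeds, evaluates, and restores the
caller's RNG state, so generating image *i* never perturbs unrelated
computations.

Default problem sizes in examples and tests (tens of images at 64–128 px) are
package choices made so that the full pipeline runs in seconds; nothing in the
code depends on them.

## 2. Preprocessing

**Enhancement** is mean filtering followed by Laplacian sharpening:
`out = clip(avg − λ·∇²avg, 0, 255)` per channel, replicate borders. With
`λ = 0` it reduces exactly to the mean filter, which the tests exploit.

**Hair removal** follows the DullRazor idea: the brightest of four oriented
grayscale closings (linear structuring elements at 0°, 45°, 90°, 135°) is
compared to the original luminance; pixels where the closing gain exceeds
`hair_threshold` are candidate hair. Two structural filters then reject
non-hair detections: components smaller than `min_stroke_area` (speckle) and
components where more than `max_thick_fraction` of pixels survive a 3×3
erosion (compact blobs — true hairs are thin, so almost none of their pixels
have a fully detected neighborhood). The surviving mask is dilated once and
inpainted by linear interpolation along the direction perpendicular to the
detected stroke orientation. Pixels outside the mask are returned
bit-identical.

The threshold (25) and the structural filters deserve a note: a pure
closing-residue threshold fires on ordinary skin texture, whose residue scales
with local texture amplitude, while true hair-to-skin contrast is an order of
magnitude larger. The values were chosen from that separation argument, not
fitted to any test outcome. Inpainting necessarily smooths texture under the
stroke; the correctness criterion is therefore "large error reduction on the
stroke, zero change off it", not per-pixel recovery.

## 3. Splitting and augmentation

`make_split()` partitions each class independently with round-half-up
arithmetic: `test = round(0.20·n)`, `val = round(0.16·n)`, `train` the
remainder, shuffled under the run seed. `round_half_up()` is implemented as
`floor(x·10^d + 0.5)/10^d` because R's `round()` uses banker's rounding,
which breaks the published count arithmetic on exact halves.

Class imbalance is handled by integer multipliers: `plan_augmentation()` maps
each class count `n` and multiplier `k` to `final = n·(k + 1)` (each original
contributes `k` augmented copies). Augmented images are random compositions of
flips, right-angle rotations, crops-with-resize and brightness scaling.
Crucially, `run_pipeline()` applies augmentation **after** the split and to
the training partition only; z-score statistics are likewise fit on training
rows only, and `evaluate_run()` refuses feature tables whose test rows leaked
into fitting. These leakage guards are tested explicitly.

## 4. Marker-controlled watershed segmentation

`segment_lesion()` runs the classic marker-controlled chain:

1. **Gradient magnitude** of the smoothed luminance (central differences by
   default, Sobel optional).
2. **Sure background** by Otsu thresholding plus a 5×5 closing.
3. A **contrast guard**: Otsu always finds a split, even in unimodal noise, so
   the foreground/background mean luminance separation must exceed
   `min_contrast` (default 15 on 0–255; noise-induced separations are ~1,
   real lesion contrasts tens of levels) or the stage fails.
4. **Euclidean distance transform** of the non-background region, with a
   `min_core_distance` gate rejecting regions with no interior.
5. **Sure foreground** at `tau · max(D)` (default `tau = 0.4`), so higher
   `tau` always yields a subset — a monotonicity property the tests assert.
6. **Markers**: 8-connected components of the foreground labeled `1..K`,
   background as label `K + 1`, everything else unknown.
7. **Flooding** (C++): a priority queue ordered by ascending gradient with
   FIFO tie-breaking grows each marker through 4-connected neighbors; every
   pixel ends in exactly one basin (an optional mode keeps watershed lines
   as 0 instead).
8. **ROI selection**: the basin with maximal overlap with the sure-foreground
   wins, subject to a minimum area `alpha_min` (default 100 px).

Failures at any stage return a structured `lesion_segmentation` object with
`failure = TRUE`, the failing `stage` and a human-readable `reason` — callers
like `run_pipeline()` degrade gracefully to a full-image mask rather than
crash.

## 5. Radiomic features (96 per image)

All texture features are computed on the masked, 16-level equal-width
quantized luminance.

* **GLSZM** (16 statistics): the size-zone matrix `P[g, s]` counts
  8-connected zones of level `g` and size `s`, enumerated by connected-
  component labeling. Statistics follow the standard IBSI formulas
  (small/large-area emphasis, gray-level and zone-size non-uniformity and
  their normalized forms, zone percentage, variances, entropy, and the four
  joint low/high gray-level area emphases).
* **GLDM** (14 statistics): the dependence matrix `P[g, d+1]` counts, for
  each masked pixel of level `g`, the number `d` of Chebyshev-1 neighbors
  within gray-level tolerance `α = 0`.
* **Color block** (16 values): per-channel 4-bin histograms (normalized),
  per-channel means scaled by 255, and the population standard deviation of
  luminance scaled by 255.
* **LBP** (50 bins): classic 8-neighbor radius-1 codes, neighbors read
  clockwise from the top-left with weight `2^(k−1)`, `neighbor ≥ center`
  setting the bit; the 256 codes are folded into 50 equal-width bins
  (width `ceiling(256/50) = 6`).

The fast implementations are validated against brute-force oracles written
with no shared code: explicit BFS zone enumeration, per-pixel neighbor
counting, and double-loop statistic formulas, agreeing to 1e-10 over batches
of random masked ROIs.

## 6. Deep features, fusion and classifiers

Deep features are global-average-pooled activations of a convolutional
backbone applied to the resized lesion ROI. A backbone **registry** separates
metadata from weights: `mobilenet_v2` (1280-dim) and `efficientnet_b4`
(1792-dim) are registered so that dimensional arithmetic (96 + 1280 = 1376,
96 + 1792 = 1888 hybrid features) and configuration work, but invoking them
errors with a clear message because pretrained weights cannot ship in a
text-only package. A deterministic `tiny_test` backbone (three 3×3
conv/ReLU/avg-pool stages, fixed-seed He-scaled weights, 32-dim output) makes
the full pipeline executable offline.

Fusion is z-score normalization per block (training statistics only) followed
by concatenation. Three classifier families are provided behind one
interface: random forests (`ranger`, with the two published profiles —
55 trees/depth 10 for radiomic-only, 100/15 for hybrid), one-vs-rest SVMs
(`e1071`, with decision-value orientation fixed against the class labels) and
a small authored feed-forward network trained with Adam and early stopping.
All are seeded and single-threaded for reproducibility.

## 7. Evaluation

`per_class_metrics()` computes one-vs-rest precision, accuracy, sensitivity
and specificity from the confusion matrix (0/0 cases are defined as 0 and
flagged). AUC is computed **twice**: as the trapezoid integral of the
empirical ROC staircase and as the Mann–Whitney statistic with midranks for
ties. These are mathematically identical; `evaluate_run()` asserts agreement
to 1e-9 on every class as a standing self-check, and the tests push this to
1e-12 including tied scores. `aggregate_overall()` macro-averages the
per-class values; reported values use round-half-up to 2 decimals.
`reference_metrics()` exposes the shipped per-class comparison table for the
two published backbone configurations.

## 8. Limitations

* The synthetic generator produces separable classes by design; absolute
  accuracy numbers on it say nothing about clinical performance.
* Only the `tiny_test` backbone is executable; the published backbones are
  registry metadata.
* Hair inpainting is 1-D linear interpolation — it removes strokes cleanly
  but flattens texture under them.
* The watershed contrast guard assumes lesions darker (or, with
  `invert_polarity`, brighter) than the surrounding skin; amelanotic lesions
  with near-zero luminance contrast will be rejected as "no lesion evidence".
* GLSZM/GLDM are 2-D, single-scale, fixed 16-level quantization; no wavelet
  or multi-scale variants are included.
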