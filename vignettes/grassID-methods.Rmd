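---
title: "Discriminating grass seedlings from images: methods and design notes"
author: "grassID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating grass seedlings from images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassID)
```

## The problem

Wheat, annual ryegrass and brome grass seedlings at the 1–4 leaf stage
are all narrow-leaf grasses of very similar appearance. Field experts
separate them by a handful of subtle cues — ryegrass leaves are narrower
with a reddish base; brome leaves are bluish-green, slightly hairy and
shiny; wheat leaves are wider and plainly green. `grassID` quantifies
exactly these cues from top-view colour images of single seedlings and
builds a component-based discriminator on them.

The pipeline assumes its input image contains one plant over a
non-green (soil-like) background, as produced by cropping a plant from a
larger scene (`cropRectangle`). Multi-plant detection, illumination
correction and camera calibration beyond the `groundResolution` utility
are out of scope.

## Segmentation model

A pixel is plant if its HSV saturation is at least `saturationMin` and
its hue lies in the foliage window `[hueLowDeg, hueHighDeg]`, default
54–154°. The window is a fixed domain constant for green foliage on soil
backgrounds; the saturation floor removes achromatic noise pixels whose
hue is numerically meaningless (we define the hue of an achromatic pixel
as 0, but the saturation gate excludes it anyway).

Tunable parameters, with defaults:

* `hueLowDeg = 54`, `hueHighDeg = 154` (degrees) — the foliage hue window.
* `saturationMin = 0.15` (fraction) — the low-saturation cutoff. The
  method description this package follows cites zeroing "low colour
  saturation" pixels without a number; 0.15 is a typical HSV noise floor
  and is configurable.
* `minRegionPx = 25` (pixels) — connected components smaller than this
  are removed as salt noise. Set 0 for strictly threshold-only
  behaviour.
* `contrastStretch = FALSE` — an optional global linear min–max stretch
  before hue conversion. Hue is invariant under a common linear scaling
  of the channels, so the stretch is cosmetic and off by default.

Grayscale intensity uses the 0.2989/0.5870/0.1140 luma weights, rounded
half away from zero (`floor(x + 0.5)`), which matters only for exact
byte-level reproducibility of the gray image.

## The eleven features

Colour features are computed per pixel and averaged over the mask.
Normalizing each channel by the pixel's own grayscale intensity removes
a common illumination factor — the indices are exactly invariant to
multiplying (R, G, B) by any positive constant. Two singularities are
handled explicitly: black pixels (intensity 0) have no defined factors
and are skipped everywhere; pixels with `r_i + b_i = 0` (blue-free pure
greens) have no defined RBI, are assigned RBI = 0, flagged, and skipped
in the RBI mean. The per-plant aggregate is the arithmetic mean — the
method we follow publishes one value per plant without stating the
aggregation; the mean is the standard regionwise statistic.

The erosion width `W` erodes the full plant mask with a 3×3 square
kernel until nothing remains and reports twice the iteration count.
Pixels outside the image are background, so regions touching the border
erode from the border inwards too (we guarantee this by padding the mask
with a zero ring before every erosion, since the underlying EBImage
kernel treats out-of-bounds pixels as foreground). Multi-leaf plants are
eroded as one region, so `W` reflects the widest surviving structure —
in practice the leaf-base disk where leaves overlap; this is documented
behaviour, not a defect. We count iterations until the region is empty
(not until a single pixel remains).

A geometric note on the Waddle Disk Ratio `WDR = W / (2√(A/π))`: the
3×3 square kernel erodes in the Chebyshev metric, so a rasterized
*Euclidean* disk of radius `r` vanishes after about `r/√2` iterations
and a disk's WDR is near `1/√2 ≈ 0.71`, not 1. WDR remains a pure
roundness-versus-linearity measure (long thin leaves score far lower),
but its absolute scale carries this kernel factor.

Texture uses the L = 256 gray-level histogram over mask pixels only.
Entropy is reported in bits (log base 2); the base is a pure rescaling
and has no effect on correlations or the component model.

## Feature selection and the component model

The redundancy filter keeps a feature iff its absolute Pearson
correlation with every already-kept feature is below 0.7, scanning in a
configurable priority order. The boundary is inclusive (|r| = 0.7 counts
as redundant), matching the published rule that variables with
|r| ≥ 0.7 form one group. The default priority promotes
`r_i, RBI, EBI, W, WDR, U_t` — with it, the filter applied to the
published eleven-feature correlation matrix reproduces exactly those six
survivors. Correlations are computed on raw features; Pearson
correlation is scale-invariant, so this is consistent with the
correlation-matrix PCA downstream.

The model is PCA of the sample correlation matrix: standardize with
sample SDs (n − 1), eigen-decompose, retain components with eigenvalue
≥ 1 − `kaiserTolerance`. The default tolerance 0.05 encodes the
borderline-inclusion practice of keeping a component whose eigenvalue
prints as 1.00 — the scree-plot-guided judgement call made in the
original calibration of this method.

Varimax rotation uses Kaiser row-normalization (the SPSS default,
exposed as `rowNormalize`) via `stats::varimax` with a 1e-8 convergence
tolerance; our conventions — columns ordered by decreasing sum of
squared loadings, dominant entry positive, the same convention applied
to unrotated loadings — make fits bit-reproducible. Tests verify the
rotation against an independent planar-angle grid search of the varimax
criterion.

Score coefficients use the regression method `B = R⁻¹ L_rot`, the
object published as a "component score coefficient matrix". Fitted
scores are then exactly standardized (mean 0, variance 1, mutually
uncorrelated over the training set), which is what makes the downstream
ANOVA's total sum of squares equal `n − 1`. The bundled
`referenceScoreCoefficients()` matrix allows scoring standardized
feature rows under the original greenhouse calibration without
refitting; `referenceCorrelations()` and `referenceEigenvalues()`
preserve the corresponding correlation matrix and retained spectrum.

## Thresholds and classification

For each species pair the discriminator is one retained component and
one threshold. Group 95% intervals use Student-t critical values (these
reproduce the published interval bounds better than a normal
approximation). The published procedure says only that the threshold
lies "between" the adjacent CI bounds of the two species; we fix the
midpoint of the gap for determinism and expose an override.

Assigning components to pairs: the original calibration fixed the plan
(first component separates ryegrass from wheat, second brome from
wheat, third ryegrass from wheat); that plan is available as
`referencePlan()`. On refitted models, however, rotated component order
and orientation are data-dependent, so the default `plan = "auto"`
assigns each species pair the retained component with the largest
standardized mean separation `|m_A − m_B| / (sd_A + sd_B)` among those
whose CIs are disjoint. We deliberately do not use the widest raw CI
gap: gap width ignores the group spreads the threshold must cope with,
and can prefer a high-variance component with well-separated means over
a tighter, more discriminating axis.

A score exactly at the threshold is assigned to the low side — an
explicit, testable tie rule. Pairs whose CIs overlap on every retained
component raise `OverlappingIntervals` rather than guessing. The
pairwise rules are the primary output; no fused three-way classifier is
fitted.

## The synthetic generator

Real greenhouse images behind the original calibration are not
deposited, so the generator stands in for them. Leaves are quadratically
curved, linearly tapered strokes radiating from a common base; colour is
a linear base-to-tip gradient plus a basal red boost decaying tipward
(`exp(−4t)`), a whole-leaf blue tint, and multiplicative grayscale
speckle that moves `U_t`/`E_t` without shifting hue. Per-plant draws add
within-species variability: an independent per-channel colour shift
(sd 8 by default) and 40% relative spreads on the red boost, blue tint
and speckle sd. Without this within-species variation every feature
would be driven by species identity alone, all features would be
mutually correlated above 0.7, and the selection/PCA stages would
degenerate to a single component — unlike real data. Realized colours
are clamped into the 58–150° hue range so the generator's documented
invariant (foliage hue inside the segmentation window) cannot be broken
by an extreme draw; strong basal red boosts may still push a few
leaf-base pixels below 54°, which mimics a genuinely reddish base and is
tolerated by the mask-F1 property rather than hidden.

The species presets encode the expert contrasts: wheat — widest leaves
(10 ± 1 px), plain green, smooth (speckle 0.04); brome — narrower
(6 ± 0.8 px), blue-green base colour plus tint, reddish base, hairy
(speckle 0.14); ryegrass — narrowest (3.5 ± 0.6 px), strongest red base,
smooth (speckle 0.03). These sit the discriminating features roughly
2.5–3.5 within-class SDs apart, comfortably above the ≥ 2 SD regime the
end-to-end property assumes, because a single-component CI-midpoint
threshold needs about 3 SD of score separation to clear 85% accuracy on
a 57-image holdout reliably. Default canvas is 200 × 200 px; leaf length
draws are truncated at mean + 3 sd so a plant always fits, and a stroke
leaving the canvas raises `CanvasTooSmall` instead of clipping
silently.

What the generator does **not** emulate: perspective and lens
distortion, shadows and specular highlights, soil texture and debris,
overlapping neighbour plants, leaf twist, and the growth-stage
progression of real seedlings. Passing tests on synthetic data therefore
demonstrate the internal correctness and statistical behaviour of the
pipeline, not field-ready accuracy on real imagery.

## Numerical choices and degenerate inputs

* Eigenvalues are clipped at 0 before taking square roots (guarding
  against −1e-16 artefacts); their sum is validated against the feature
  count to 1e-8.
* Zero-variance features raise `DegenerateColumn` at standardization and
  correlation; a constant score vector raises `ZeroWithinVariance` in
  the ANOVA (detected exactly, per group, before floating-point fuzz).
* An empty mask raises `EmptySegmentation` at every feature operation.
* Crop rectangles are 0-based, row-major, half-open; out-of-range crops
  raise `OutOfBounds`.
* Feature CSVs are written with 17 significant digits so the
  feature-table path and the in-memory path produce bit-identical
  models; all artifacts are written to a temp file and renamed, so
  outputs are atomic.
* Bonferroni p-values are `min(1, m · p)` with `m = k(k−1)/2`.

## Problem sizes used by the tests

The checked-in suite fits the model on feature tables of 286 synthetic
plants (118/122/46 class balance, 229 train / 57 holdout), runs the
erosion oracle on random masks up to 32 × 32, the varimax grid-search
oracle on 6 × 3 loadings, factor recovery at n = 500, and segmentation
F1 on 10–15 rendered plants per check. These sizes give stable
statistics while keeping a full test run in the low minutes on one CPU.

## Known limitations

* The erosion width of a multi-leaf rosette measures the thickest
  overlap region, not the individual leaf blade width.
* The pairwise thresholds assume unimodal, roughly symmetric score
  distributions per species; heavy overlap yields
  `OverlappingIntervals` rather than a degraded threshold.
* The correlation filter is greedy: it guarantees pairwise |r| below
  the cutoff among survivors but not an optimal subset.
* Segmentation has no shadow/highlight model; very dark or clipped
  pixels fail the saturation gate and are lost to the mask.
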