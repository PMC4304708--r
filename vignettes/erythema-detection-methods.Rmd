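---
title: "Erythema-based actinic keratosis detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Erythema-based actinic keratosis detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akdetect)
```

## The problem

Actinic keratoses (AK) are keratinocyte dysplasias of chronically
sun-exposed skin, typically presenting as erythematous, often scaly macules
on the face, scalp and dorsal forearms.  Clinical counting of AK is
notoriously variable, both between raters and for the same rater over time,
which confounds treatment decisions and trial endpoints.  `akdetect`
implements an automated, fully repeatable reading of standardized clinical
photographs that targets the single most salient visual feature of AK:
erythema.

The package covers the complete protocol around the detector as well:
object-level evaluation against rater annotations, parameter tuning by
cross-validated grid search, the group statistics used to compare high- and
no-lesion populations, and a synthetic-scene generator with exact ground
truth so that every stage can be validated without clinical data.

## The detection model

For a photograph $I$ with channels $R, G, B \in [0,1]$ the pipeline is:

1. **Chroma transform.** Full-range BT.601 YCbCr; the *erythema intensity
   map* is $E = (C_b + C_r)/2$.  On skin fields, erythematous regions are
   local maxima of $E$.  An achromatic pixel maps to $E = 0.5$ exactly, so
   a colourless image produces no detections whatsoever.
2. **Guided filtering** (self-guided, window edge $w$, regularization
   $\epsilon$): within each $w \times w$ window the output is the local
   linear model $a = \mathrm{var}/(\mathrm{var} + \epsilon)$,
   $b = (1-a)\,\mathrm{mean}$, averaged over all windows covering a pixel.
   This removes sensor noise and fine skin texture while preserving lesion
   edges whose local variance exceeds $\epsilon$.
3. **Top-hat by reconstruction.**  $E$ is eroded with a discrete Euclidean
   disc of radius $r$ and geodesically reconstructed under $E$; the
   difference $E - \mathrm{open}_r(E)$ isolates bright peaks too small to
   contain the disc, with their shapes preserved exactly (unlike a plain
   opening).  The disc radius is therefore an upper bound on the scale of
   detectable lesions.
4. **Hysteresis thresholding.**  A pixel survives iff it is $\ge t_{low}$
   and 8-connected through $\ge t_{low}$ pixels to some pixel
   $\ge t_{high}$.  This discards low-contrast fluctuations while keeping
   the full extent of any region whose core is convincing.

8-connected components of the binary output are the detected lesions,
ordered deterministically by the raster position of each component's
top-left-most pixel.

### Parameters

| parameter | meaning | unit | default preset (face / arm) |
|---|---|---|---|
| `window_px` | guided filter window edge (0 = no smoothing) | px | 41 / 21 |
| `epsilon` | texture regularization | (map units)$^2$ | 1 / 0.1 |
| `disc_radius_px` | reconstruction disc radius | px | 60 / 50 |
| `t_low` | hysteresis low threshold | map units | 0.005 / 0.003 |
| `t_high` | hysteresis high threshold | map units | 0.007 / 0.008 |

The presets (`ak_params()`) are the values selected by the original
clinical tuning at roughly 10 px/mm; on images at a different scale the
spatial parameters should be rescaled or re-tuned.  Thresholds are on the
unit-scaled peak map, which is why they are small: a strongly erythematous
lesion raises $E$ by only a few hundredths.

## Numerical and representational choices

These points were genuinely open when the package was designed; the choices
and their rationale:

* **YCbCr dialect.** Full-range (JPEG/JFIF) BT.601 on `[0,1]`, chroma
  offset 0.5.  Threshold magnitudes of order $10^{-3}$–$10^{-2}$ are
  consistent with a unit-scaled map, and full-range is the photographic
  convention.  A limited-range (`"studio"`) transform is available in
  `rgb_to_ycbcr()` so the convention is explicit; the detector always runs
  full-range.
* **Chroma mean, not difference.** Erythema raises $C_r$ but *lowers*
  $C_b$, so averaging them partially cancels the signal; the map is
  implemented exactly as the mean because that is the published detector's
  definition, and the tuned thresholds compensate.
* **Window semantics.** `window_px` is the square window *edge* and must be
  odd (or 0 = identity); even windows have no centre pixel.
* **Borders.** All box means normalize over the truncated window inside the
  image, which keeps the guided filter exactly shift-equivariant and avoids
  padding artefacts at frame edges.  Erosion treats out-of-frame pixels as
  $+\infty$ (window truncation) for the same reason.
* **Connectivity.** Geodesic reconstruction uses the 4-connected (3×3
  cross) elementary dilation; hysteresis and component labelling use
  8-connectivity so diagonal lesion boundaries are not split.
* **Matching rule.** A detected lesion and a reference lesion co-localize
  when either centroid, rounded half-up to the nearest pixel, lies inside
  the other's pixel set.  Detected lesions are visited in raster order and
  matched to the first eligible unmatched reference lesion; surplus matches
  to an already-claimed lesion count as false positives, so nothing is
  double-counted.
* **Degenerate denominators.** Pixel sensitivity with an empty reference
  and PPV with an empty detection are reported as `NaN` and excluded from
  aggregation; F2 is 0 when either component is 0.  Pixel metrics across
  multiple images are pooled over pixels rather than averaged per image, so
  images without annotated lesions contribute their false positives without
  producing undefined ratios.
* **Tie-breaks.** Grid search resolves F2 ties towards the smallest
  `(window, epsilon, disc, t_high, t_low)` lexicographically, making tuning
  runs bit-reproducible.
* **Minimum lesion size.** Raters circumscribe only lesions above a
  clinical size cut-off (about 2 mm); the automated pipeline applies no
  size filter by default because the published detector has none, but
  `filter_min_size()` provides the equivalent-circle-diameter rule as an
  option.
* **Border components** of the binary mask are counted as lesions; nothing
  in the protocol suggests discarding them.

## Cross-validated tuning

`nested_loocv()` holds out one volunteer at a time (all of their
photographs), grid searches the remaining volunteers' images for the
parameters maximizing pooled pixel-level F2
($F_2 = 5 s p / (4 p + s)$, weighting sensitivity twice as heavily as PPV),
then applies the selected parameters to the held-out volunteer.  Reported
metrics pool the held-out pixels of all folds, so they carry no tuning
optimism.  The inner step is a plain grid search on the training
volunteers rather than a second leave-one-out layer: the selected
parameters are only ever consumed by the outer held-out evaluation, and a
second nesting level would multiply cost without changing what is
reported.  Face-type and arm-type photograph groups are tuned
independently, which is how the published per-site presets arise.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders a skin-toned field at 10 px/mm (the middle of
the typical 9–11 px/mm acquisition range) with:

* a base skin tone plus a smooth low-frequency mottle field (amplitude
  0.02, mostly luminance with a slight chroma imbalance so the erythema map
  sees a small, realistic nuisance) and i.i.d. pixel noise (sd 0.01);
* elliptical lesions with a raised-cosine radial profile (no hard rims,
  which no real lesion has and which the guided filter would preserve
  unrealistically), colour-shifted along the +R/−G direction so the
  erythema map rises by `erythema_shift` (default 0.04) at the centre;
* dark circular confounders mimicking nostrils and eye corners: a pure
  luminance drop by default, invisible to an ideal erythema detector, with
  an optional chroma shift to reproduce anatomical-structure false
  positives.

The ground-truth label marks each lesion's core — pixels whose planted
elevation exceeds 25% of the peak — i.e. the visibly erythematous region a
rater would circumscribe, not the mathematically nonzero tail of the
profile.  Lesion centres are packed with pairwise separation of at least
the sum of radii plus 5 px (and at least one maximum radius), so planted
lesions never overlap and never merge in the label mask; a scene too
crowded to satisfy this is rejected rather than silently rendered.

Cohorts (`generate_cohort()`) emulate the two study arms: high-burden
scenes carry 10–40 lesions, lesion-free scenes none, and both keep 2–6
confounders.  In cohorts the confounders receive a jittered chroma shift
(0.03 ± 50%) by default, because the study's lesion-free group produced
distinctly nonzero automated counts driven by anatomical structures — that
false-positive floor is precisely what the group comparison measures.
Sub-seeds derive deterministically from the master seed by counter, so any
cohort is reproducible at any size.

Passing tests on these scenes demonstrate that the pipeline, matching and
tuning machinery are correct and that the detector recovers what it is
designed to see.  They do not demonstrate clinical performance: the
generator has no specular highlights, hair, scale (hyperkeratosis),
three-dimensional shading, background, or erythema of non-AK origin, and
its lesions are cleaner and better separated than real fields of sun
damage.  The published clinical correlations and group means depend on the
original photographs and are deliberately not restated as package results.

## Problem sizes used in validation

The shipped validation runs are scaled to desk hardware as a deliberate
design choice: five 256×256 scenes (~50 lesions) for the recovery check, a
4-volunteer × 2-image cohort with a 96-combination grid for the nested
LOOCV demonstration, and 10-scene-per-arm cohorts for the group
comparison.  Stage results are cached per `(window, epsilon, disc)` during
grid search, so the full LOOCV demonstration completes in well under a
minute; the published full-scale grid (thousands of combinations over 100
photographs) is the same code path at larger inputs.

## Known limitations

* Erythema is the only feature: lesions presenting with scale but little
  redness are invisible by construction, and any non-AK erythema
  (psoriasis, rosacea, irritation) will be detected.
* No background segmentation or hair removal is performed; the method
  assumes framed, evenly lit skin fields on a neutral backdrop.
* The co-localization rule is centroid containment; elongated or
  horseshoe-shaped regions whose centroid falls outside themselves can
  defeat it in either direction.
* Spatial parameters are resolution-bound; photographs far from
  ~10 px/mm require re-tuning.
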