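---
title: "Methods: 3D immune-cell scoring of PD-L1 in fluorescence z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D immune-cell scoring of PD-L1 in fluorescence z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icscore3d)
```

## The problem

The SP142 immune-cell (IC) score — the percentage of tumor area covered by
PD-L1-expressing tumor-infiltrating immune cells — gates access to
PD-1/PD-L1 checkpoint inhibitors at a 1% clinical cutoff. Conventional IHC
reads one 4-µm section of a heterogeneous three-dimensional lesion.
Optically cleared, immunofluorescence-stained 200-µm slices imaged
confocally as z-stacks (nuclear counterstain, membrane counterstain, and a
PD-L1 marker channel) allow the score to be recomputed at many depths and
averaged, exposing cases whose classification flips from layer to layer.

`icscore3d` implements the computational side of that workflow: per-layer
tumor/immune segmentation, mask algebra and IC scoring, depth-profile
analysis, 2D-vs-3D concordance statistics, pseudo-bright-field rendering for
visual QC, and a synthetic phantom generator that provides exact ground
truth so every stage is testable without imaging data.

## The scoring model

For each analysed layer $z$ the pipeline produces:

* a **tumor-cell mask** from the tumor segmentation model;
* a **merged tumor-area mask** $A_{\mathrm{tumor}}$: morphological closing
  (disc radius `closing_radius_px`, default 20 px) followed by filling of
  enclosed holes up to `max_hole_px` (default 5000 px), so intratumoral
  stroma counts toward tumor area as the SP142 interpretation convention
  requires;
* an **immune mask**, split exactly into intratumoral
  ($\mathrm{IC} = \mathrm{immune} \cap A_{\mathrm{tumor}}$) and peritumoral
  parts;
* a **PD-L1⁺ IC mask** $A_{\mathrm{IC}^+}$: intratumoral immune cells whose
  marker signal crosses a positivity threshold.

The layer score is

$$\mathrm{IC\ score}(z) = 100 \cdot \frac{A_{\mathrm{IC}^+}(z)}{A_{\mathrm{tumor}}(z)} \quad [\%],$$

with categories: 0% → negative, (0, 1)% → borderline, ≥ 1% → positive (the
lower bound of the positive class is closed). Areas are raw pixel counts;
the score is a ratio and therefore invariant to lateral calibration.

Layers with zero tumor area carry no defined score (the denominator
vanishes); they are flagged `no_tumor` and excluded from all 3D summaries
rather than scored 0.

### Marker positivity

Clinical positivity is binary and independent of staining intensity, but a
pixel threshold must still be chosen. The default derives it by Otsu's
method from the marker histogram restricted to the immune mask, **floored at
the background level** (mean + 4 SD of the marker outside the immune mask):
plain Otsu degenerates on unimodal data and would split pure noise when no
marker signal exists. A fixed numeric threshold can be configured instead;
either way the resolved value is logged.

Positivity is then decided per cell (default `mode = "component"`): an
8-connected component of the intratumoral immune mask counts as a PD-L1⁺
cell when at least `min_pos_frac` (default 5%) of its pixels cross the
threshold, and the whole cell footprint enters the numerator. This matches
how a membrane-localised stain is read (a stained ring marks the whole cell
positive) and is robust to isolated hot noise pixels. A `mode = "pixel"`
variant returns the thresholded pixels themselves.

### DCIS handling

Only invasive carcinoma should be scored. A tumor model trained without
in-situ examples will include DCIS in the tumor-area mask, inflating the
denominator and underestimating the score. `layer_ic_score()` accepts an
oracle DCIS mask and an `exclude_dcis` flag; exclusion removes DCIS pixels
from the denominator and the numerator-eligible region. The flag is **off by
default**, reproducing the uncorrected behaviour; switching it on with a
half-DCIS phantom exactly doubles the score, demonstrating the mechanism in
reverse.

## Depth profiles

Stacks are acquired at a 1.4 µm z step and analysed every 7 µm
(`select_layers()`: stride = round(interval/spacing) = 5, indices 0, 5, 10,
…). For one case the profile summarises:

* `average_score_pct` — the unweighted mean over layers with a defined
  score (no weighting is applied because none is specified clinically);
* min, max, range, and `crossing_1pct` = (min < 1 ≤ max);
* a pattern label from the per-layer categories: `uniform_negative`,
  `uniform_expressed` (every layer borderline or positive),
  `heterogeneous_presence` (expressing and negative layers coexist), plus a
  separate `category_crossing` flag when layers sit on both sides of 1%;
* `immune_area_range_frac` = (max − min)/max of per-layer immune area;
* the 2D comparison: the reference section (for phantoms, the exact truth of
  the most superficial layer, where adjacent histology sections would be
  cut) against the category of the 3D average, yielding `concordant`,
  `3d_higher` or `3d_lower` on the ordinal scale
  negative < borderline < positive. Discordance is categorical because the
  clinical decision is categorical; the raw score delta is reported
  alongside.

Cohort-level agreement uses `agreement_table()`: a 3×3 confusion matrix and
the overall percent agreement (trace/n × 100).

## Segmentation

Two models run in sequence — tumor first, then immune — on the two
counterstain channels only (the marker channel is reserved for positivity).
The model family used in the original workflow is not prescribed, so the
package provides two implementations behind one interface:

* **Default small model** (`train_segmenter()`): per-pixel weighted logistic
  regression on multiscale convolutional features — raw nuclei/membrane
  intensities, Gaussian means at σ = 2, 4, 8 px, a membrane Gaussian, and a
  local standard deviation at σ = 4 px that separates dense nuclear texture
  from flat background. No deep-learning runtime is available in the target
  environment, and the pipeline, not any particular architecture, is the
  object under test; a U-Net would slot behind the same `segmenter`
  interface. Class imbalance is handled by a foreground weight equal to the
  background/foreground ratio capped at 20. Training subsamples a fixed
  number of pixels per patch under a seed; aliased (constant) features get
  zero coefficients; non-convergence (e.g. on perfectly separable data) is
  reported as a warning, never silently ignored.
* **Classical baseline** (`classical_segmenter()`): nuclei-channel threshold
  plus component size filtering — components ≥ 150 px for tumor (nuclei
  overlap into large clusters), 12–120 px for immune (small isolated round
  cells). Fully deterministic; it is the oracle route that makes end-to-end
  tests independent of training.

Patch preparation follows the standard protocol: 256 × 256 patches assigned
8:1:1 to train/validation/test by a seeded permutation (`make_patchset()`).
Full-layer inference tiles logistic models at the training patch size with
50% overlap and averages probabilities before one global threshold of 0.5,
so seams cannot create mask artifacts. Evaluation (`evaluate_pixelwise()`)
reports exact integer confusion counts with pixel accuracy, precision,
recall and IoU; IoU (and precision/recall) are defined as 1 when their
denominator is empty. Pixel accuracy is the headline metric because that is
how the original models were evaluated, but it flatters sparse classes —
the immune model reaches ~94% accuracy at an IoU near 0.34, because
foreground-weighted training trades precision for recall on a ~3% foreground
class. IoU is therefore always reported alongside.

## The phantom: a stated world

`generate_case()` renders 3-channel stacks emulating cleared breast-cancer
specimens:

* geometry defaults follow the acquisition: z step 1.4 µm (143 layers span
  a 200-µm slice), lateral calibration 0.621 µm/px;
* **tumor nests**: disc regions constant through depth (tumor area is
  near-uniform across layers, as observed), densely filled with overlapping
  elliptical nuclei (semi-major 8–12 px) clipped to the nest;
* **immune cells**: small circles (radius 3–5 px) placed per layer, inside
  nests and in the surrounding stroma, each surrounded by a 2-px nuclear
  moat so the two classes are separable by morphology alone — exactly the
  information the real models have;
* **marker**: a membrane ring on a designed subset of intratumoral immune
  cells. The per-layer designed fraction is realised by greedily marking
  whole cells until their footprint area best matches
  `fraction × tumor area`; the residual is bounded by half a cell footprint
  (≤ ~0.4 percentage points at the default tumor area, typically far less);
* **DCIS** (optional): a tumor-cell-filled disc bounded by an unbroken
  bright membrane ring (myoepithelial surrogate), never containing immune
  cells;
* **noise and depth attenuation**: additive Gaussian noise (σ = 0.05 on
  unit-scale intensities) clipped to non-negative, and a multiplicative
  `exp(-decay × depth)` dimming. The decay default is 0 because exported
  stacks are assumed depth-normalised (acquisition compensates laser power
  with depth); tests exercise decay > 0 explicitly.

All randomness flows from one integer seed through a local RNG; generation
is bitwise reproducible and never touches global RNG state.

What the phantom does **not** emulate: optics (PSF, scattering,
cross-talk), 3D cell continuity across layers (cells are placed per layer,
which is sufficient for a per-layer scoring pipeline but means adjacent
layers are statistically, not physically, correlated), realistic nuclear
pleomorphism, and vendor normalisation curves. A green test therefore
establishes the correctness of the *pipeline logic and its estimators* on
morphologically separable input — not performance on real tissue.

## Numerical choices and edge cases

* Coordinate convention: `(z, y, x)`, 0-based z indices in all reports;
  `depth_um = z × z_spacing_um`.
* Morphology uses an exact Euclidean distance transform (Felzenszwalb
  two-pass, with a large finite sentinel instead of infinity to avoid NaN
  envelopes on empty rows); dilation is `EDT ≤ r²`, erosion is the dual,
  closing is dilate-then-erode. Hole filling labels 4-connected background
  components and fills those not touching the border and not larger than
  the cap.
* `merge_tumor_area` is extensive, monotone and idempotent; the closing
  radius (20 px ≈ 12 µm) is large enough to bridge inter-nuclear stroma and
  small enough not to merge separate nests at default geometry. These are
  configuration values, not biological claims.
* Whether the score denominator is the merged area or tumor-cell pixels
  only is not specified anywhere authoritative; the default is the merged
  area (interpretation-guide convention), and the tumor-cell mask is kept
  so the alternative is one call away.
* Scores are validated into [0, 100]; `categorize()` is total on that
  interval and errors outside it.
* TIFF I/O is a minimal built-in baseline codec (little-endian,
  uncompressed, 8/16-bit unsigned and 32-bit float, JSON metadata in
  ImageDescription) because no TIFF package ships with the target R
  installation; round-trips are exact for masks and single-precision for
  intensities, and interoperability is tested in both directions against an
  independent Python reader/writer.

## Known limitations

* The logistic pixel classifier is a deliberately small stand-in: it meets
  the scaled-down accuracy analogues on phantom data but is not expected to
  match a trained CNN on real immunofluorescence.
* Immune-model precision on sparse foreground is low at the default
  recall-oriented weighting (see above); the classical segmenter or a
  higher probability threshold is preferable when false-positive immune
  area matters.
* Designed fractions above ~0.3 can become unrealisable at default geometry
  (not enough intratumoral space for non-overlapping cells); the clinically
  relevant range exercised throughout is 0–5%.
* Cohort statistics are descriptive (percent agreement, confusion counts);
  no inferential statistics are computed.
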