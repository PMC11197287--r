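---
title: "Automated scratch-assay wound quantification with scratchseg"
author: "scratchseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scratch-assay wound quantification with scratchseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In vitro scratch (wound-healing) assays quantify cell migration: a confluent
monolayer is mechanically scratched, imaged at successive time points, and
the shrinking cell-free area measures how quickly cells close the wound —
the standard readout for therapy efficacy in wound-healing studies.
Manual delineation of the wound boundary is slow and user-dependent, and
classical tools tend to straighten uneven edges and to round spindle-shaped
migrating cells. `scratchseg` implements a fully automated pipeline:
semantic segmentation of the cell-free region by encoder–decoder networks,
followed by pixel-count wound areas and percentage errors against ground
truth.

The pipeline stages are:

1. **Preprocessing** — contrast-limited adaptive histogram equalization
   (CLAHE) of the RGB image, area-based downscaling to a working resolution
   of 1024×768, and conversion to floating point in `[0, 1]`.
2. **Quadrant augmentation** — every image and mask is split into four
   equal spatial quadrants (512×384 at working resolution). This both
   quadruples the training set and sharpens edge learning; after
   prediction, the binarized quadrants are merged back exactly.
3. **Segmentation** — a 5-level U-net, U-net++ (nested dense skips) or
   Attention U-net (gated skips), all built from one shared configuration
   so only the skip-path topology differs; conv–BN–ReLU blocks, 2×2 max
   pooling, and a sigmoid head emitting per-pixel cell probabilities.
4. **Training** — soft dice loss, Adam at learning rate `1e-3` with a 0.9
   per-epoch exponential decay, batch size 4, a fixed epoch budget, no
   early stopping.
5. **Quantification** — probabilities are binarized at a strict 0.5
   threshold (ties fall to wound), quadrants are merged, and the wound area
   is the count of mask-0 pixels; the signed percentage error against the
   ground-truth area is `(WA_pred − WA_gt) / WA_gt × 100`.
6. **Evaluation** — DSC, accuracy, IoU, precision, recall, specificity and
   rank-based ROC-AUC with the *wound* as the positive class, macro-averaged
   per image.

Masks follow the labelling convention of the assay literature: white (1) =
cell-containing region (ROI), black (0) = wound.

## The synthetic-data generator

Real assay images are rarely redistributable, so the package ships a seeded
generator whose scenes have exact ground truth and emulate the features
that matter for this task:

* a **textured cell sheet** (Gaussian random field, correlation length
  `cellTextureScale`, sd 0.14 around `cellIntensityMean`) against a
  **low-texture wound band** at `woundIntensityMean` — local texture
  contrast is precisely the signal that texture-based tools and the
  networks exploit;
* a wound band of fractional width `woundWidthFrac` whose edges deviate
  from a straight line by a smooth pseudo-periodic profile bounded by
  `edgeRoughnessAmp`;
* **closure**: at closure fraction c the band is eroded inward to `(1−c)`
  of its fresh width, with the roughness scaled down alongside, so bands at
  increasing closure are strictly nested — wound area is provably
  nonincreasing in c and the fully closed wound is the all-cell mask;
* **migrating spindle cells**: elongated rotated ellipses (labelled as
  cells) stamped inside the band;
* multiplicative radial **vignetting** and additive Gaussian **noise**.

Every scene is a pure function of `(SceneParams, seed)` — bitwise
reproducible. With zero roughness and no migrating cells the wound area
equals the analytic band area to the pixel, which anchors the area
arithmetic in tests.

Defaults were chosen once so that the scenes are realistic for a
brightfield assay *and learnable*: the cell-free dish is slightly brighter
(0.66) than the cell sheet (0.42), the texture sd (0.14) keeps the two
intensity distributions mostly separated while leaving local texture as the
more reliable cue, spindle cells are at least ~2 px wide (thinner cells are
unresolvable at the working scale), and `simulateDataset()` samples closure
fractions from U(0, 0.6). The upper bound deliberately avoids near-closed
wounds: the percentage error divides by the ground-truth area, so it is
ill-conditioned as the wound closes (and undefined at closure 1) — the same
regime the assay literature reports as its worst case.

What the generator does **not** emulate: phase-contrast optics, cell
debris, proliferation versus migration dynamics, focus drift, or the
staining variability of real cultures. Passing tests on synthetic scenes
therefore demonstrate that the pipeline's machinery is correct and that the
models can learn texture-defined boundaries; they do not certify
performance on any particular real dataset.

## Preprocessing choices

**CLAHE clip-limit semantics.** Implementations disagree on what the clip
limit means. Here `clipLimit` is the fraction of the tile's pixel count at
which histogram bins are clipped (so the default 0.005 clips each of the
256 bins at 0.5% of the tile's pixels); the clipped excess is redistributed
uniformly and per-tile CDF mappings are interpolated bilinearly between
tile centres. A zero-contrast tile keeps the identity mapping, making a
constant image an exact fixed point. The implementation agrees with
`EBImage::clahe` (correlation > 0.99 on matched settings, after converting
the clip fraction to EBImage's bins-relative limit) but additionally
supports 1×1 grids, arbitrary image sizes and the degenerate-tile identity.
Applied twice, CLAHE at the default clip limit shifts pixels by < 0.06 mean
absolute intensity relative to one application (empirical tolerance,
asserted in the tests).

**Colour handling.** CLAHE is applied to the Rec.601 luminance channel and
the RGB channels are rescaled by the luminance ratio (hue-preserving);
independent per-channel equalization is available as an option.

**Downscaling.** Images are downscaled by exact pixel-area-overlap
averaging (the INTER_AREA rule), expressed as two one-dimensional weight
matrices; this preserves total brightness to numerical precision and is
exact for integer factors. Upscaling is out of scope. Masks are *never*
area-averaged — that would manufacture non-binary boundary values — but
downscaled nearest-neighbour and re-binarized at 0.5.

## The CNN engine

No deep-learning framework is used: the package contains a small seeded CNN
engine written against BLAS matrix products, with tensors laid out
`(channels, height, width, batch)`. A 3×3 convolution is nine shifted
channel-mixing multiplications; transposed 2×2 stride-2 convolutions,
batch normalization, ReLU, 2×2 max pooling (first-maximum tie-break),
channel concatenation, additive attention gates and bilinear upsampling
complete the op set. Reverse-mode gradients come from a tape of backward
closures; the test suite verifies every variant's gradients against central
finite differences (agreement well below 1e-4 relative error, typically
~1e-9). Because the engine is pure R,
training is bit-for-bit reproducible for a given seed — there is no
framework nondeterminism to tolerate.

Weights use He initialization scaled by fan-in, biases start at zero, and
batch-norm running statistics (momentum 0.9) are used at inference while
batch statistics are used during training.

## Architectures

All three variants share encoder/decoder blocks (two conv–BN–ReLU layers
per level, filter widths doubling from `baseFilters`); the published level
widths of the reference networks are not fully specified, so 16 filters at
level 1 (doubling per level) is the default and all in-package comparisons
are made at identical configurations.

* **U-net** — plain skip concatenation.
* **U-net++** — the nested grid `X[i][j]`, where node `(i, j)` receives all
  previous same-level nodes plus the upsampled coarser node; deep
  supervision is off (single sigmoid head on the last top-level node),
  keeping the three variants comparable under one threshold step.
* **Attention U-net** — before concatenation, each skip is modulated by an
  additive attention gate: 1×1 projections of the skip and of the upsampled
  decoder signal are summed, ReLU'd, projected to a scalar field and passed
  through a sigmoid; the gate multiplies the skip features. This strictly
  increases the parameter count over the plain U-net, which the tests
  assert. (Whether U-net++ has more or fewer parameters than U-net depends
  on unpublished width choices, so no such inequality is asserted.)

The decoder upsamples with transposed convolutions by default; a fixed
bilinear-upsample + 1×1 convolution variant is available.

## Training protocol

* soft dice loss `1 − (2Σpg + ε)/(Σp + Σg + ε)` on the sigmoid cell
  probabilities, ε = 1e-6. The exported `diceLoss()` defaults to scoring
  the *wound* class (`1−p` against `1−g`) so that `1 − diceLoss` on
  binarized maps equals the wound-positive DSC exactly; the training loop
  uses the native cell-probability form, which in controlled desk-scale
  comparisons converges measurably faster at identical budgets.
* Adam (β₁ = 0.9, β₂ = 0.999), learning rate `1e-3` decayed per epoch by
  0.9 (staircase `lr_e = lr0 · 0.9^(e−1)` — the simplest reading of an
  exponential decay schedule, applied per epoch rather than per step).
* batch size 4; a fixed epoch budget (50 by default) and no early stopping.
* per-epoch training dice/loss are means over batches; validation dice is
  the soft dice of overlap sums accumulated over the whole validation set
  in inference mode.

**Splitting.** `makeSplits()` draws `round(0.10 n)` test images, then
splits the remainder 90:10 (round-half-away). For n = 400 this yields
40/324/36 — note an exact 90:10 of 360 cannot yield 325/35, so the exact
rule is implemented and `splitSpec()` lets any externally published index
lists be injected verbatim. Splits are drawn over whole images *before*
quadrant tiling, so the four patches of one image can never leak across
sets. `makeCvFolds()` produces k near-equal folds serialized to JSON so
every model variant consumes identical folds.

## Quantification and evaluation conventions

* **Strict threshold**: probability 0.5 itself maps to wound; only values
  strictly greater become cell.
* **Wound as positive class**: TP are pixels correctly predicted as wound.
  DSC = 2TP/(FP+2TP+FN), IoU = TP/(TP+FP+FN), PRE = TP/(TP+FP),
  REC = TP/(TP+FN), SPE = TN/(TN+FP), ACC = (TP+TN)/total.
* **Zero denominators**: a metric with a vanishing denominator returns 1
  when the counts force agreement (the class is absent from both masks) and
  raises an error otherwise — silent sentinel values would hide degenerate
  evaluations.
* **ROC-AUC** is the Mann–Whitney rank statistic of the wound score
  (`1 − p`) against wound labels, average ranks on ties (constant maps
  score 0.5). Some tools compute AUC on binarized masks; that mode exists
  as an explicit option (`onBinarized = TRUE`) but is not the default.
* **Percentage error** keeps its sign to distinguish over- from
  under-segmentation; a fully closed ground truth (area 0) is an error, not
  a 0 or an infinity.
* **Aggregation** is the per-image macro average (the mean DSC of the
  evaluated images), not the pooled-pixel metric; the two differ on
  imbalanced images and the tests demonstrate the difference.
* External tool masks are ingested from lossless files and re-binarized at
  0.5 after scaling to `[0, 1]`; a resolution mismatch is an error, never an
  implicit resample.

## Problem sizes in tests and the acceptance script

The test suite and `scripts/acceptance.R` exercise the full pipeline at
desk scale: 40 synthetic scenes generated at 256×192, preprocessed to
128×96, split 4/32/4, quadrant-tiled to 64×48 patches, and used to train a
depth-3, 8-filter plain U-net for 10 epochs (batch 4, lr 1e-3, decay 0.9).
These sizes were chosen so the whole study runs in a few minutes on one CPU
core while leaving every stage — including learning itself — genuinely
exercised; the held-out checks require mean DSC ≥ 0.90 and mean absolute
percentage error ≤ 10%, a desk-scale analogue (not a reproduction) of the
high-DSC / few-percent-PE regime reported for full-scale assay datasets.
Structural checks on the 512×384×3 full-size input run at reduced filter
widths, where the shape contracts are width-independent.

## Known limitations

* The engine is CPU-bound pure R: fine for desk-scale studies and testing,
  not for 50-epoch training on hundreds of 512×384 patches.
* Synthetic scenes are statistically much cleaner than real microscopy;
  absolute metric values on them overstate what any model would achieve on
  real data.
* Batch-norm statistics come from small batches (4); models trained briefly
  can show train/inference discrepancies, which the validation-dice curve
  makes visible.
* `woundArea()` counts pixels; converting to physical units (µm²) is left
  to the caller, as magnification metadata is not modelled.
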