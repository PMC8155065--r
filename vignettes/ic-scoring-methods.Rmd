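---
title: "Methods: rule-based PD-L1 (SP142) IC scoring and ring-study statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based PD-L1 (SP142) IC scoring and ring-study statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1ic)
```

## The scoring model

The SP142 immune-cell score is defined as the fraction of the tumor area
occupied by PD-L1-stained immune cells of any intensity. `pdl1ic`
quantifies it on an 8-bit RGB patch in five deterministic steps:

1. **HSV thresholding.** DAB-stained immune cells separate from
   hematoxylin-stained tissue far better in hue than in RGB. Each pixel is
   mapped to HSV and kept when it falls inside a closed threshold box;
   the default box is [101, 175] for hue, [40, 120] for saturation and
   [40, 150] for value, in the `hue179` convention (hue 0–179 = degrees/2,
   S and V 0–255).
2. **Morphological denoising.** An opening — 3×3 erosion followed by 3×3
   dilation — removes speckle smaller than the kernel while restoring the
   surviving stained regions.
3. **Region exclusion.** PD-L1 staining is not specific to immune cells:
   tumor cells in the epithelium also stain. Epithelium and necrosis masks
   are predicted (or supplied), and
   `M_IC = M_stain AND NOT (M_epithelium OR M_necrotic)`.
4. **Gap filling.** Aggregated immune cells are scored by the enclosing
   area of the aggregation, so `M_IC` is dilated iteratively to close
   inter-cell gaps.
5. **Ratio.** The score is the set-pixel count of the dilated mask divided
   by the total pixel count `N` of the patch, then binned into the
   2-category (<1% / >=1%) and 4-category ([0,1), [1,5), [5,10),
   [10,100] percent) schemes.

### Assumptions

* Stained-pixel chromaticity is stable enough that a fixed HSV box
  separates stain from background; `calibrate_thresholds()` re-derives the
  box from annotated pixels when it is not.
* The patch is the scoring unit: no tiling, no whole-slide handling, no
  scanner color management.
* Region exclusion quality bounds scoring quality; the oracle provider
  isolates the rule-based scoring from segmentation error.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| threshold box | [101,175]/[40,120]/[40,150] | HSV units (`hue179`) | separates DAB-stained IC pixels from tissue |
| calibration coverage | 0.95 | fraction | per-channel symmetric-quantile interval keeping 95% of annotated stained pixels |
| denoise kernels | 3×3 square | px | smallest opening that kills single-pixel speckle |
| dilation iterations | 2 | count | gap filling for aggregated cells; `calibrate_dilation_iterations()` chooses it from reference areas when available |
| positivity cutoff | 1 | % | treatment stratification boundary |
| segmenter threshold | 0.5 | probability | mask binarization; anti-monotone in the threshold |

Numerical conventions: threshold bounds are inclusive on both ends (the
box is written with closed intervals); category bins are half-open
`[lo, hi)` with the last bin closed, so a score of exactly 1% is positive;
interpretation bands are likewise half-open with the top value in the top
band. Scores are fractions internally and percent in user-facing output.

Two HSV scale conventions are supported (`hue179`, `hue255`) because
threshold values are only meaningful relative to a channel range; the
default is `hue179`, under which the default box's hue ceiling of 175 sits
just inside the 0–179 range. A patch and a box must declare the same
convention or thresholding refuses to run.

### Open choices and how they were made

* **Score denominator.** The ratio's `N` is all patch pixels by default
  (the literal reading of the formula); a guideline-style variant that
  removes necrotic pixels from the denominator is available via
  `scoring_config(denominator = "exclude_necrotic")`.
* **Calibration trimming.** "Keep 95% of stained pixels" does not say
  from which tail; we trim symmetrically (2.5% each side) with
  inverse-ECDF quantiles, which guarantees at least the requested coverage
  per channel and is monotone in the coverage level.
* **Morphology borders.** Pixels outside the image are treated as unset
  for both erosion and dilation (zero padding), so a full-frame mask erodes
  at the borders rather than being preserved by edge replication.
* **Multi-class AUC from hard labels.** Raters emit a category, not a
  probability, so one-vs-rest AUC uses proximity of the predicted ordinal
  index to the target class as the decision value, support-weighted across
  classes present in the gold labels. For a binary scheme this reduces to
  the usual rank AUC.
* **Fleiss' kappa CI.** Asymptotic standard error of the classic
  formulation with a normal approximation by default; a seeded bootstrap
  over items (2,000 resamples) is available via `ci = "bootstrap"`.
* **Group comparisons.** Per-experience-group breakdowns are reported
  (acceptance analysis, per-rater ICC), but no between-group significance
  machinery is included.

## The segmentation stand-in

Epithelium and necrosis detection in production systems is a deep
encoder–decoder network. This package ships a miniature analog designed to
be trainable on a desktop in seconds: each channel is Gaussian-smoothed at
several spatial scales (the downsample/upsample context path of an
encoder–decoder) and concatenated with the native-resolution channels (the
skip connection); a small MLP head maps each pixel's feature vector to a
foreground probability. Training minimizes per-pixel mean squared error by
seeded minibatch SGD with inverted dropout (keep 0.8), random flip
augmentation, and a geometric learning-rate schedule. Two independent
single-role models (epithelium, necrotic) are trained rather than one
multi-class head.

The default configuration (300 epochs, learning rate 1e-2 decaying to
1e-5, batch 64) describes a full-scale recipe; the tests and the
acceptance script use a desk-scale recipe (25 epochs, learning rate 2
decaying to 0.1) because the tiny MLP head trains with far larger steps
than a deep network. On synthetic patches, whose regions are color-coded,
the desk-scale run reaches held-out IoU well above the 0.7 bar the test
suite asserts. This says nothing about real IHC: real epithelium is not
separable by color statistics alone, and the stand-in makes no claim to
the original network's accuracy. The `oracle_region_provider()` exists
precisely so that scoring correctness can be established independently of
segmentation quality.

## What the synthetic generator emulates

`generate_patch()` builds a patch from layered ground truth:

* **Regions.** Epithelium and necrosis are smooth random fields
  (thresholded blurred Gaussian noise) hitting the requested area
  fractions exactly; defaults 30% and 5%.
* **Cells.** Immune cells are discs of radius 7 px (jittered ±1), matching
  a 7–10 µm lymphocyte at the 0.524 µm/px scale the patches declare.
  `scattered` places them uniformly in the stroma; `aggregated` uses a
  parent–offspring cluster process (offspring spread 4 cell radii);
  `mixed` mixes both. Discs are added until the requested raw IC fraction
  is met exactly, the final disc trimmed nearest-first.
* **Colors.** Each layer draws per-pixel HSV values uniformly from its
  box: stain from the detection box shrunk by a 2-unit margin (so every
  stained pixel survives the 8-bit HSV–RGB–HSV round trip and is
  detectable by construction), pale low-saturation stroma, strongly
  saturated hematoxylin-like epithelium, desaturated necrosis — all
  disjoint from the stain box on the saturation channel.
* **Non-specific staining.** A configurable fraction of epithelial pixels
  (default 2%) is colored from the stain box as cell-sized discs — discs,
  not salt-and-pepper, because single stained pixels would be erased by
  the denoising opening, which is not how tumor-cell staining behaves.
* **Two truth areas.** `true_ic_fraction_raw` counts IC pixels;
  `true_ic_fraction_hull` is the area after a morphological closing with a
  disc of twice the cell radius — the enclosing-area notion that
  gap-filling dilation is calibrated against.

What it does *not* emulate: nuclei texture, stain intensity gradients,
scanner variation, tissue folds, or any real histological structure.
Passing the recovery tests therefore demonstrates the correctness of the
scoring rules and their implementation, not clinical performance on real
slides.

`generate_rater_table()` models rater `r` scoring image `i` as
`clip(true_i + bias_r + noise, 0, 1)` with a per-rater bias fixed across
rounds (SD 0.01) and fresh per-cell noise (SD 0.02, optionally scaled per
experience group). This is the minimal model under which consistency
ICC(3,1) and absolute-agreement ICC(2,1) separate: bias is invisible to
the former and penalized by the latter. Defaults mirror the ring-study
shape of 31 raters (11 senior / 10 intermediate / 10 junior), 109 images,
3 rounds. True scores default to a skewed mixture (55% below 2%, 30% in
2–10%, 15% in 10–40%) so that borderline images near the 1% cutoff —
the known driver of categorical discordance — are well represented.

## Statistical definitions

ICC(3,1) and ICC(2,1) come from the two-way ANOVA mean squares
(`MSR` items, `MSC` raters, `MSE` residual):

* ICC(3,1) = (MSR − MSE) / (MSR + (k−1) MSE), CI from the F interval on
  MSR/MSE.
* ICC(2,1) = (MSR − MSE) / (MSR + (k−1) MSE + k(MSC − MSE)/n), CI by the
  Satterthwaite-df F construction.

Fleiss' kappa uses the classic per-item agreement and marginal category
proportions. All three are validated in the test suite against
independent oracles (mean squares assembled from `aov()`, the direct
kappa formula evaluated spreadsheet-style, and `pROC` for binary AUC).

Interpretation bands: ICC — poor < 0.5, moderate < 0.75, good < 0.9,
excellent ≥ 0.9; kappa — weak from 0.4, moderate from 0.6, strong from
0.8, near perfect from 0.9, and "below weak" under 0.4.

The acceptance analysis classifies each (rater, image) pair: *fully
accepted* if the absolute difference between rater and AI score is below
1% and both fall in the same 4-category bin; *almost accepted* at 5% with
the same-bin requirement (reading the bin-change exclusion against the
4-category scheme); *categorically accepted* per scheme if the bins match.

## Problem sizes and degenerate inputs

The test suite and acceptance script run at deliberately small sizes
chosen as the package's standard desk-scale study conditions: 256×256
patches (a stand-in for 2160×2160 clinical patches), 50-patch recovery
sweeps over IC fractions 0.2%–20%, 96×96 patches and 10+5 images for
segmenter training, 100 replicates of 200-image × 10-rater tables for CI
coverage. Degenerate inputs are defined rather than accidental: empty
masks score 0; a blank patch scores 0; zero dilation iterations return the
mask unchanged; calibration ties resolve to the smallest iteration count;
one-category rating tables raise a degenerate-table error; ICC estimates
at exactly 1 report no CI rather than a spurious one.

## Known limitations

* The HSV channel ranges behind the published threshold box are an
  interpretation (`hue179` default); if the upstream convention differs,
  recalibrate or switch conventions.
* The segmentation stand-in is a correctness vehicle, not a model of real
  epithelium; IoU results on synthetic patches do not transfer.
* Scores at category edges are intrinsically unstable: a sub-0.1%
  estimation error flips the bin for a patch whose true fraction sits on
  an edge. The recovery tests therefore assert category agreement away
  from edges (±0.2 percentage points) while holding the continuous-score
  error bound everywhere.
* Fleiss' kappa's asymptotic CI is known to be approximate at small item
  counts; use the bootstrap option when it matters.
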