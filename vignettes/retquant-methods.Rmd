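---
title: "retquant: models, synthetic data and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retquant: models, synthetic data and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retquant)
```

This vignette is the package's own account of what it computes, which
assumptions the computations rest on, and where the design was genuinely
open.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A B-scan is a normalised intensity matrix (values in [0, 1], depth in rows,
lateral position in columns) with an isotropic pixel size in mm.  The
working geometry is 256 × 1600 px; widths must be divisible by 16 so scans
can be partitioned into vertical clips.  A desk-scale profile of 128 × 512
(32 clips) is used throughout the tests; nothing in the code depends on the
absolute scale.

**Layer detection** treats EZ/ELM integrity as a clip-level presence
problem: a scan is split into 16-px-wide clips, a binary CNN scores each
clip, and per-image predictions are the ordered concatenation of clip
decisions.  The *length rate* of a layer is the fraction of positive clips.
Consequences of this formulation worth knowing:

* the length rate is quantised to 1/n_clips (1/32 at desk scale, 1/100 at
  full scale);
* a clip is labelled positive if the layer is annotated in *any* of its 16
  columns (the annotation is per-column; nothing forces a rule for
  partially annotated clips, so the any-column rule is fixed here and used
  consistently by the generator, the labels and the quantifier — which is
  what makes the round-trip identity exact);
* no sub-pixel boundary position is estimated; presence only.

One independent binary model is trained per layer rather than a two-output
model; the two tasks share no labels and this keeps each training set
balanced on its own terms.

**Lesion segmentation** is multi-class with mutually exclusive labels
(softmax over {background, IRF, SRF, SHRM, PED}); lesion masks are disjoint
regions anatomically, so per-pixel argmax is the right output space.  The
original large pretrained backbone is replaced by a small U-shaped
encoder–decoder (3 levels, 8/16/32 channels, batch norm, nearest-neighbour
upsampling with skip concatenation) because acceptance runs must need no
download and train on one CPU in minutes.  Two desk-scale choices deserve a
note:

* *Row-coordinate channel* (default on): IRF and SRF share reflectivity and
  differ mainly by depth relative to the RPE; a full-scale network has the
  receptive field to learn that context, the desk-scale one does not, so
  the input gets a second channel that is simply the normalised row index.
* *Class weighting* (default median-frequency): background is ~90% of
  pixels at desk scale, and an unweighted pixelwise cross-entropy spends
  most of its gradient there.  Both choices are configuration flags
  (`coord_channel`, `class_weights = "none"`) and were fixed before the
  acceptance floors were frozen.

**Quantification** turns predictions into the 12-feature vector: EZ/ELM
length rates; per-lesion area = pixel count × (pixel size)², summed over
connected components; maximum diameter = the largest horizontal (column)
extent over 4-connected components × pixel size — the basal-diameter
convention for lesions measured along a B-scan (a max-Feret alternative was
considered and rejected as needlessly different from clinical practice);
mean reflectivity of SHRM and PED on the min-max-normalised image (the
original reflectivity units are unstated, so normalised units are used and
declared).  An absent class has area 0, diameter 0 and *missing*
reflectivity — missingness is information (the lesion resolved) and is kept
as `NA` until the modelling layer imputes it explicitly.

## 2. Evaluation

Dice, accuracy, sensitivity and specificity are computed per scan — at
pixel level for the blocky lesions, at clip level for EZ/ELM (which is why
layer specificities sit far below the near-1 pixel specificities of rare
lesion classes: the clip-level negative class is small).  Dice is undefined
for the linear layers and reported N/A.  Dice of two empty masks is defined
as 1 (agreement on absence) and logged as a convention, not a theorem.
Point estimates are means over scans; intervals are percentile bootstrap
over scans (the original CI construction is unstated; the output labels the
method).  The AVG column is the arithmetic mean across biomarkers of the
per-biomarker point estimates, reported to 3 decimals.

## 3. The prognosis model

Outcome classes are 0 = stable (fluid resolved, solid lesions persist),
1 = PDA (persistent activity), 2 = cured (all lesions resolved).  The
design matrix for a horizon stacks visit blocks and signed
later-minus-baseline deltas:

| horizon  | blocks                                          | columns (six-metric) |
|----------|--------------------------------------------------|----|
| baseline | baseline                                         | 12 |
| month1   | baseline, month1, Δmonth1                        | 36 |
| month3   | baseline, month1, month3, Δmonth1, Δmonth3       | 60 |

Missing reflectivity cells are imputed as 0 with an appended indicator
column per affected column, so the forest can split on "the lesion is
gone" separately from "the lesion is dark".

The forest is CART (Gini) + bagging + majority vote, `mtry = floor(sqrt(p))`,
implemented in the package (no forest package is assumed by the runtime
environment).  Evaluation is stratified 10-fold cross-validation; the tree
count is grid-searched over 150…800 in steps of 50 *inside each training
fold* on a stratified inner split, selected by macro one-vs-rest AUC — the
original account does not say whether its grid search was nested, and
nesting is the choice that cannot leak; it is recorded in the report
metadata (`chosen_n_trees`).  Multi-class AUC is the unweighted mean of
one-vs-rest AUCs of the vote fractions; macro sensitivity/specificity are
unweighted means of per-class one-vs-rest values of the hard votes (the
3-class averaging rule is unstated in the original; macro is declared
here).  Ties in majority voting break to the lowest class index,
deterministically.  Feature importances are impurity decreases accumulated
over the CV forests, normalised to sum to 1.

## 4. What the synthetic data states, and what it does not

The generator renders the stated world the package is tested in: a dark
vitreous / medium neuroretina / bright RPE band / dim choroid slab; EZ and
ELM as 1–3-px bright lines with *one contiguous seeded gap* each (contiguous
rather than per-column noise so clip labels are meaningful); IRF ellipses in
the neuroretina, SRF pockets above the RPE, SHRM between retina and RPE,
one PED dome seated on the RPE band — qualitatively the lesion topology of
real nAMD scans; multiplicative Gaussian speckle `x(1 + σε)` clipped to
[0, 1] (σ = 0.08 by default).  The default pixel size 8/1600 mm reflects an
8-mm lateral scan span at full width; depth scaling is assumed isotropic
because no axial calibration is stated anywhere.  Ground-truth features are
measured on the pre-noise rasterisation with the same raster definitions
the quantifier uses, so quantification on emitted annotations inverts the
generator exactly; the acceptance tolerance (1 px of discretisation) is a
bound, not a target.

Longitudinal cohorts draw per-eye trajectories.  In the default
(`signal = "lesions"`) mode, resolve/persist archetypes are drawn with the
46.5 / 33.1 / 20.4% stable/PDA/cured prevalences and labels are assigned by
applying the outcome rule to the *realised* rasterised features — labels
and features cannot disagree by construction.  In `signal = "ez_only"`
mode, lesion courses are drawn independently of outcome and only the
EZ/ELM gap trajectory carries class information (PDA below a month-3 EZ
length rate of 0.6, cured at 0.9); this is the cohort on which the claim
"the two photoreceptor-integrity features dominate" is *literally true* and
therefore testable.

What the generator deliberately does not emulate: real OCT speckle
statistics (multiplicative Gaussian is a stress test, not a physical
model), curved retinal geometry, motion/shadow artifacts (excluded from the
original data too), vessel shadows, and any claim about real lesion
morphology distributions — lesion sizes are free parameters.  A green test
therefore establishes that the pipeline's machinery is correct and
trainable, *not* that the desk-scale networks would reach the original
clinical performance; the original headline numbers are reproducible only
as in-table arithmetic (the AVG aggregations and cohort proportions in
`scripts/acceptance.R`); the clinical headline metrics themselves are out
of reach for synthetic desk-scale runs and are not claimed.

## 5. Numerical choices and degenerate inputs

* Min-max normalisation maps a constant image to all zeros with a warning
  rather than erroring: constant frames occur in masked regions.
* Bilinear interpolation for intensities, nearest-neighbour for label
  masks and trace columns (labels must never be interpolated); half-pixel
  centre convention throughout, so identity-size resizes are exact.
* Batch normalisation uses batch statistics in training and running
  averages at inference, making `segment()` and `detect_layers()`
  deterministic functions of (weights, input); training batches of one clip
  are skipped (a single-sample batch has no variance).
* All stochastic entry points take explicit seeds and run in a private RNG
  scope that restores the caller's `.Random.seed`; stage seeds are derived
  from the pipeline seed and stay below 2³¹.
* The clip positivity threshold is 0.5 (unstated in the original,
  configurable).
* Gradient correctness of the hand-written conv / batch-norm / pooling /
  softmax code is itself under test against central finite differences.

## 6. Known limitations

* The PED inferior-border refinement alluded to in the original account is
  unspecified there and not implemented; no PED-specific border rule
  exists in this package.
* Detection is presence-only; no layer row positions are regressed.
* The segmenter is 2-D per B-scan; no volumetric context.
* Whether the original "length rate" was measured in trace pixels rather
  than clip proportion is ambiguous; the clip-proportion reading is
  implemented (the two coincide at 16-px granularity up to quantisation).
* Bootstrap CIs resample scans; if the original resampled pixels or used a
  binomial approximation its intervals would differ.
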