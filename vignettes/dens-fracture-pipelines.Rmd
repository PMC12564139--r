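---
title: "Windowing, radiomics and segmentation quality in dens fracture detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowing, radiomics and segmentation quality in dens fracture detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(densCT)
```

## The scientific question

Fractures of the dens (the odontoid process of C2) are small, often subtle
findings on cervical-spine CT with serious consequences when missed. Two
automated detection strategies compete for this task:

* a **direct classifier** ("M1"): a 3D CNN with a feed-forward head that maps
  the whole volume to a fracture probability, with no anatomical prior; and
* a **two-stage pipeline** ("M2"): a segmentation network first isolates the
  dens, quantitative radiomic features are extracted from the segmented
  region, and a classical machine-learning classifier makes the call.

The two-stage route raises two methodological questions that this package is
built to study quantitatively:

1. **How much does CT windowing matter?** Contrast adjustment (bone window,
   gamma correction, histogram percentile windowing, CLAHE, ROI-based
   windowing) changes both what a network sees and what radiomic features
   measure.
2. **How robust is the radiomics stage to imperfect segmentation?** A
   deployed segmenter will not produce perfect masks; if classification
   accuracy collapses as the Dice similarity coefficient (DSC) of the mask
   degrades, the two-stage design is clinically fragile.

Because clinical CT datasets of this kind are not freely redistributable,
every experiment in the package runs on **synthetic bone phantoms** whose
statistical structure mimics dens CT: the package is an instrument for
studying the *methodology*, not a re-derivation of any clinical result.

## The phantom generator

`generateCase()` builds a piecewise-constant anatomy and then degrades it:

* a cylindrical dens with a bright cortical shell (default 1200 HU) around a
  trabecular core (300 HU), standing in soft tissue (40 HU);
* optionally a planar fracture cleft of configurable width (default 1.5 mm,
  within the 1-2 mm range of acute fracture lines) at a configurable tilt
  from the transverse plane; cohort jitter draws the tilt uniformly within
  +/-30 degrees, matching the transverse-to-oblique cleft orientations seen
  clinically. Cleft voxels take soft-tissue intensity. A displaced fracture
  shifts the distal fragment rigidly by an integer number of voxels —
  sub-voxel shifts are deliberately excluded so the generator never
  introduces a resampling confound;
* partial-volume blending is emulated by a Gaussian blur along z (default
  SD 1 mm) rather than true slice averaging: it is cheap and gives monotone
  control of partial-volume severity;
* Gaussian noise (default 20 HU) plus extra soft-tissue heterogeneity
  (10 HU) are added last.

The default grid is 64^3 voxels at 0.6 x 0.6 x 1.2 mm — anisotropic like
routine cervical protocols (sub-millimetre in-plane, 1-2 mm slices). All
randomness flows from a single per-case seed derived from
`(cohort seed, case index)`, so cohorts are reproducible and
order-independent. `generateCohort()` defaults to a fracture prevalence of
79/366, the class imbalance of a representative clinical cohort.

What the phantoms deliberately do **not** model: beam hardening, metal
artifacts, anatomical neighbours (C1 arch, skull base), and realistic
trabecular texture. Passing tests on phantoms therefore demonstrate that the
pipeline's plumbing, metrics and robustness claims are correct — not that
any particular accuracy carries over to patient data.

## Windowing methods

All six transforms map an HU volume into [0, 1] (`applyWindowing()`):

| method      | definition | defaults |
|-------------|-----------|----------|
| `none`      | min-max scaling | — |
| `bone`      | clip((v − (WL − WW/2)) / WW, 0, 1) | WL 400 HU, WW 2000 HU |
| `bone_gamma`| bone window then v^γ | γ ∈ {0.5, 1, 2} |
| `histogram` | linear map of [p5, p95] of the whole image | 5th/95th percentiles |
| `clahe`     | slice-wise contrast-limited adaptive histogram equalization | 8x8 tiles, clip 0.01 |
| `roi`       | [p5, p95] computed inside the mask + surroundings, applied globally | 3 mm dilation |

Numerical choices worth stating: percentiles interpolate linearly between
order statistics (the same rule as the brute-force sort oracle used in the
tests); the "immediate surroundings" of the ROI are a 3 mm Euclidean
dilation computed with an exact distance transform, so anisotropic voxels
are handled correctly; CLAHE's clip limit is expressed as the fraction of
tile pixels a histogram bin may hold before its excess is redistributed, and
constant slices are passed through unchanged (a flat histogram has no
contrast to redistribute, and this keeps pure-background slices stable).
CLAHE is the one transform that is not a global monotone point map — it is
monotone only within each tile mapping, which is its purpose.

## Radiomics

`extractFeatures()` produces a fixed 23-feature schema: 14 first-order
(moments, percentiles, energy, histogram entropy in bits, uniformity), 4
shape (volume, surface area, sphericity, elongation), 5 GLCM texture
(contrast, correlation, energy, homogeneity, entropy) averaged over the 13
unique distance-1 3D offsets. Implementation decisions, all stated in the
function documentation and enforced against brute-force enumeration oracles
in the test suite (relative tolerance 1e-9):

* moments use population (biased) definitions; kurtosis is Pearson (not
  excess);
* discretization defaults to a fixed bin count of 32 within the ROI min-max;
  a fixed count is robust across windowing methods that rescale intensities,
  which is exactly the comparison this package makes. Radiomics is computed
  on the windowed [0, 1] volume rescaled by 1000, so bin widths remain
  meaningful across methods;
* surface area counts exposed voxel faces rather than a mesh: it is exact,
  has an exact brute-force oracle, and is documented as systematically
  larger than mesh-based area;
* co-occurrences are counted only between voxel pairs that are both inside
  the mask, symmetrized per offset, normalized per offset, and features are
  averaged over offsets (not computed on an averaged matrix);
* a single-voxel ROI has no texture: the GLCM block gets sentinel 0 and the
  vector is flagged `degenerateTexture`.

## Neural models

Both networks are compact, pure-R implementations (im2col convolutions over
BLAS matrix multiplies) with exact analytic gradients, Adam, and a
plateau-reduce learning-rate scheduler (patience 10, cooldown 10, factor
0.1). Training defaults follow a standard regime for this task family:
initial learning rate 0.001 for the classifier and 0.01 for the segmenter,
weight decay 1e-6, at most 50 epochs at batch size 4, and an oversampling
schedule presenting fracture cases 10x and non-fracture cases 3x per epoch,
with inverse-prevalence class weights in the loss.

* **Segmenter**: a two-level 3D U-Net (DoubleConv encoder, pooled DoubleConv
  bottleneck with twice the channels, nearest-neighbour upsampling, skip
  concatenation, DoubleConv decoder, 1x1x1 output convolution), trained on
  an equal mix of soft-Dice and class-weighted cross-entropy (the mix
  weights default to 0.5/0.5). The checkpoint with the best validation Dice
  is returned.
* **Direct classifier**: DoubleConv blocks with max pooling, then a
  five-layer feed-forward head with dropout 0.1 and softmax output; the
  best-validation-accuracy checkpoint is returned.

Augmentation (`augmentCase()`) applies random scaling in [0.8, 1.2], mirror
flips per axis with probability 0.5, and a random crop to the input shape
rejected until at least 90% of the dens mask survives.

Two imbalance-handling notes. First, oversampling and inverse-prevalence
class weights both correct the same imbalance; applied together at full
strength they over-weight the fracture class (at desk scale this reliably
drives the small classifier to all-fracture predictions). `trainM1()`
therefore derives its default class weights from the *post-oversampling*
epoch composition, so the weights compensate only the residual imbalance;
explicit `classWeights` override this. Second, the desk-scale sanity runs
train with augmentation disabled: with an optimization budget of roughly a
hundred steps, the jittered cohort already supplies the variation, and
on-the-fly augmentation mainly slows convergence at this scale. Both
mechanisms remain on by default for larger budgets.

**Problem sizes.** The package's experiments run at desk scale by choice:
32^3 inputs, base channel width 2-4, batch 2-4, and cohorts of 60 phantoms.
The clinical-scale settings (120^3 crops from 256^3 standardized volumes)
remain expressible through `trainingConfig(inputShape = c(120, 120, 120))` —
the architecture is unchanged in kind, only in width. Exact DoubleConv
channel counts and FNN widths are declared configuration, not reproductions
of any published architecture.

## Segmentation quality and the stability analysis

`perturbToDSC()` degrades a mask to a chosen Dice coefficient. From the
closed form `DSC = 2(|A|-k) / (2|A|-k+m)` it computes how many deletions `k`
and additions `m` are needed (balanced in mixed mode), then applies them at
randomly chosen boundary voxels — erosion sites for deletions, dilation
shells for additions. Boundary-local flips were chosen over scattered
salt-and-pepper flips because they mimic plausible segmentation error;
scattered flips would be adversarial specifically for texture features, and
the mode is configurable so both regimes can be studied. Because `k` and `m`
fix the Dice exactly regardless of which boundary voxels are flipped, the
achieved DSC is deterministic given the mask size; tolerance 0.005 is
reached for masks of a few hundred voxels and up. Perturbed masks stay
within a two-layer dilation of the original.

`stabilityAnalysis()` runs the full two-stage pipeline for every (DSC level,
windowing method, classifier) cell. It perturbs *oracle* masks rather than
collecting real segmenter outputs so the DSC axis is exactly controlled;
grouping genuine segmenter outputs by achieved DSC is possible through
`segSource = "trained-model"` but conflates mask quality with whatever else
distinguishes hard cases. Cells are independent and each is seeded, so the
grid is reproducible and order-independent. The default DSC range,
0.82-0.94, covers the segmentation quality range a competent 3D U-Net
reaches on this task across windowing methods.

## Experiment layer and data hygiene

`splitDataset()` sizes splits by floor (train) / round (validation) /
remainder (test), so 366 cases at 0.70/0.10/0.20 give exactly 256/37/73. The
validation split is used for neural checkpoint selection only; classifiers
train on the training split alone by default (`includeValidation` exists but
is off). Standardization statistics and the zero-variance feature filter are
computed from training data only; a planted marker feature that is constant
in training and informative only in test cases provably cannot change
predictions, and the test suite and acceptance script both verify this.

The dens-centroid evaluation crop uses the mask centroid (with even window
sizes the tie breaks toward the lower index); where a published workflow
would locate the dens manually, the mask centroid is the only automatable
choice.

## Known limitations

* Phantom realism is deliberately limited (see above); absolute accuracies
  on phantoms are optimistic.
* The pure-R networks are CPU-bound; clinical-scale training (256^3 volumes,
  50 epochs) is out of reach, and the smoke-scale runs demonstrate
  correctness of the training machinery rather than model capacity.
* Whether radiomics should be computed on windowed or raw-HU intensities is
  a genuine design fork; the package defaults to windowed (that is the
  comparison of interest here) and raw-HU extraction is available by
  windowing with `none`.
* KNN vote ties cannot occur at the default odd k = 5 with two classes;
  exact distance ties are resolved by the backend's ordering.
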