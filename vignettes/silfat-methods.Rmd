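---
title: "Estimating body fat distribution from binary silhouettes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body fat distribution from binary silhouettes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Body-mass index and waist circumference are cheap to measure but conflate
two very different kinds of central adiposity: visceral fat (VAT), which
surrounds the abdominal organs and carries cardiometabolic risk, and
abdominal subcutaneous fat (ASAT), which sits under the skin and is
metabolically far more benign. Gluteofemoral fat (GFAT) may even be
protective. Whole-body MRI resolves the three depots but cannot be deployed
at population scale. The hypothesis this package operationalises is that a
person's *outline* — a pair of binary coronal and sagittal silhouettes —
carries enough shape information to estimate VAT, ASAT and GFAT volumes and,
most interestingly, the VAT/ASAT ratio, a marker of unhealthy fat
distribution that is nearly independent of BMI and waist circumference.

`silfat` implements the full analysis chain: silhouette construction from
volumetric images, a multi-task convolutional regressor trained under
nested cross-validation, linear anthropometric benchmark models, and the
downstream disease-association analyses. Because the real imaging cohort is
access-controlled, the package ships a synthetic body-phantom population
whose statistical structure emulates the study cohort; every claim the test
suite makes is made on those phantoms.

## The phantom population

Each phantom is a stack of elliptical axial cross-sections: head, neck,
torso, two arms and two legs. Abdominal slices carry a concentric
three-band structure — a VAT core, a lean abdominal wall, and a
subcutaneous ASAT ring — while hip and thigh slices carry a GFAT shell.
Ellipse stacking keeps every depot volume analytically controllable and
label-exact; the voxel labels are the generative truth, so "MRI-derived"
truth volumes are simple voxel counts times the voxel volume.

Three latent factors drive a phantom:

* **size** (`size_factor`, log-SD 0.10): a global girth scale. Depot
  volumes scale as `size^2.5`, which propagates the girth variance to a
  realistic depot-volume variance.
* **fat-distribution axis** (`vat_asat_shape`, standard normal): shifts
  abdominal fat between the visceral core and the subcutaneous ring at
  *fixed waist perimeter*, and simultaneously changes the abdominal
  cross-section eccentricity (deeper/narrower for visceral builds, with a
  slight anterior shift of the belly centre). The eccentricity coupling is
  essential: it is the silhouette-visible signature of fat distribution.
  Without it the latent axis would be invisible to any method operating on
  the outline, and the central claim — that silhouettes out-predict
  anthropometrics for VAT/ASAT — could not hold even in principle. Waist
  circumference, by construction, cannot see this axis (the perimeter is
  held constant via the Ramanujan approximation), mirroring the clinical
  observation that a tape measure cannot distinguish VAT- from ASAT-driven
  central obesity.
* **gluteofemoral scale** (`gfat_factor`): thickness of the GFAT shell.

Per-sex depot targets default to the study population's marginals
(male VAT/ASAT/GFAT 5.0/5.9/9.3 L, female 2.6/7.9/11.3 L, with matching
SDs); the lognormal loadings are solved from those targets, so realized
sex-stratified means land within a few percent of them. The latent axis is
independent of size, which keeps `|cor(BMI, VAT/ASAT)| < 0.1`, emulating
the near BMI-independence of the ratio. A residual log-SD (`sigma_resid`,
default 0.12) adds depot variation not expressible in shape; setting it to
0 produces the "shape-driven" cohorts used for model-recovery experiments,
where depots are deterministic functions of the outline and the regressor's
ceiling is limited only by learning quality.

What the phantoms deliberately do not model: anatomy beyond stacked
ellipses (no organs, no MRI physics, no pose variation), and total body
mass is leaner than the real cohort (the stylised limbs and torso carry
less volume than real bodies at matched girths, so mean BMI is ~20 rather
than ~27). Girths, depot volumes and their covariance structure — the
quantities the analyses consume — are calibrated; absolute BMI level is
not, and all disease models standardize BMI within sex, so only its
variation matters. Passing tests on phantoms demonstrate that the
*machinery* is correct and that the method recovers known structure; they
say nothing about performance on real bodies.

Disease labels follow a logistic model in sex-standardized VAT/ASAT ratio,
BMI and age (plus a small imaging-centre intercept), with per-disease
baseline prevalences and odds ratios taken from the study's reported
associations (e.g. type 2 diabetes OR/SD 1.78 male, 1.97 female). Incident
events are exponential-hazard with analogous hazard ratios, administratively
censored at a per-participant Uniform(0, 5.6 y) time so the realized median
follow-up is 2.8 years; prevalent cases are excluded from the risk set.

## Silhouette construction

The pipeline mirrors the acquisition chain: series merging (trilinear
resampling to the finest spacing, default 3.0 × 2.232 × 2.232 mm z/y/x,
overlap de-duplication), per-axial-slice body segmentation (Otsu threshold,
largest 4-connected component, hole filling), OR-projection in the coronal
(`any` over the anterior-posterior axis) and sagittal (`any` over
left-right) planes, nearest-neighbour aspect correction for the anisotropic
voxels, and composition of the two panels — coronal left — into the fixed
237 × 256 binary input image.

Choices the source description leaves open, fixed here and exposed in
configuration: the projection is a *filled shadow* (any voxel along the
ray), with a `outline` flag for the 1-pixel boundary variant; the 256
columns split 128/128 between panels; every resize is nearest-neighbour
followed by a 0.5 re-threshold so the image stays exactly binary; panels
are centred in their frames. Waist and hip circumference are measured as
marching-squares contour perimeters at the widest abdominal and gluteal
slices; the binary mask is anti-aliased with two 3 × 3 box-smoothing passes
first, since contouring a raw binary mask inflates perimeters by ~6%
through staircasing (a 150 mm circle then measures within ~1% of 2πr).

## The multi-task regressor

No deep-learning framework is assumed: the package carries its own compact
convolutional engine (im2col + GEMM convolutions in C++, Adam, early
stopping), deterministic given its seed. The default trunk is three blocks
of 3 × 3 convolution → ReLU → 2 × 2 average pooling (channels 4/8/16) over
a 60 × 64 block-averaged silhouette, followed by a 32-unit fully connected
layer and a linear head per task (VAT, ASAT, GFAT, ratio). A plain
sequential trunk was chosen over densely connected blocks: at this scale
(~30k parameters, ~2,000 training images) dense connectivity adds
bookkeeping without measurable benefit. The ratio head is trained directly
on standardized targets rather than derived as VAT/ASAT (a config option
derives it instead); all four heads share the trunk embedding, and
per-task loss weights default to 1 on standardized targets, which makes
the tasks commensurable.

Optimisation defaults — Adam at 1e-3, batch 64, at most 30 epochs,
patience 5 on the inner-validation loss — were fixed from the
linear-signal recovery experiments (a target that is a deterministic
function of the silhouette must be recovered with R² ≥ 0.95) before any
cohort-level evaluation.

### Nested cross-validation

The cohort is split into five partitions. Outer model *m* trains on
partitions {m, m+1, m+2}, uses m+3 for testing and collects unbiased
predictions on validation partition m+4; across the five models the
validation partitions tile the cohort exactly once. Within each outer
training set, an inner 3-fold cross-validation trains three networks (each
early-stopped on its held-out inner fold); the fold's prediction is their
mean-ensemble, de-standardized to liters. Target standardization uses
training-split statistics only. `audit_folds()` verifies from stored
provenance that no participant was predicted by a model trained on them.

## Benchmarks and comparisons

Sex-stratified ordinary least squares comparators share the same outer
folds and out-of-fold discipline: `BMI` (age + BMI), `Waist` (age + waist),
`WHR`, `Anthro` (age + weight + height + BMI + waist + hip + WHR + five
bioimpedance channels) and `Silhouette` (age + the network's out-of-fold
prediction — i.e. the silhouette estimate enters a linear model exactly
like an anthropometric variable). Performance is R² and MAE with
percentile-bootstrap 95% intervals (1000 paired resamples by default; BCa
was considered and not adopted — at these sample sizes the percentile
interval's coverage is verified directly by simulation in the test suite).
Model differences use paired resampling: the same bootstrap indices for
both models.

## Disease associations

Prevalent disease: sex-stratified logistic regression of disease on the
sex-standardized exposure (OR per SD), adjusted for age and imaging centre,
optionally BMI and waist circumference. Incident disease: Cox
proportional-hazards (Efron ties) on the same covariates with centre as a
stratum, prevalent cases excluded. Quintile gradients collapse
sex-stratified quintiles to Q1 / Q2–4 / Q5 (ties broken by stable rank).
Standardized prevalence within BMI-category × waist-category cells uses
marginal standardization (g-computation): fit the adjusted logistic model,
predict every participant under counterfactual cell membership, average;
intervals by bootstrap over participants. BMI bounds default to the WHO
cuts 18.5/25/30/40 with "severely obese" ≥ 40, and elevated-waist cutoffs
default to 102 cm (male) / 88 cm (female) with per-BMI-subgroup overrides
available — the exact cutoff table used by the source analysis is not
public, so these are configurable defaults.

## Numerical choices and problem sizes

* Cohort phantoms are rasterised at 6.0 × 4.464 × 4.464 mm (twice the
  acquisition spacing); single-phantom operations default to the
  acquisition spacing. The coarser grid changes depot volumes by well under
  1% while making 2,000-phantom cohorts practical on a single core.
* Recovery experiments use the sizes at which their targets are stated:
  n = 20,000 tabular participants for logistic/Cox effect recovery (100
  disease-simulation replicates over one fixed covariate draw), a
  2,000-phantom shape-driven cohort for the nested-CV experiment, 200
  simulated datasets for bootstrap-coverage calibration.
* Degenerate inputs are errors, not silent results: empty phantoms,
  background-only projections, zero-variance targets, zero ASAT in a
  ratio, rank-deficient comparator designs (the collinear columns are
  named), logistic separation, and zero-event Cox fits.
* All randomness flows through explicit integer seeds; every artifact
  written to disk carries a config hash and package version string.

## Known limitations

* The phantom geometry is stylised; its total mass and limb proportions
  are not calibrated, only girths and depot volumes are.
* The regressor is desk-scale by design. Its out-of-fold R² on shape-driven
  phantoms (≥ 0.9 for VAT at n = 2,000) reflects a cohort whose depots are
  exact functions of shape; real-image performance is out of scope here.
* Marginal standardization intervals ignore uncertainty in the quintile
  cutpoints themselves.
* The series merger assumes axially stacked acquisitions with consistent
  in-plane extent after resampling.
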