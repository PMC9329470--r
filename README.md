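# silfat — body fat distribution from binary body silhouettes

`silfat` estimates **visceral (VAT)**, **abdominal subcutaneous (ASAT)** and
**gluteofemoral (GFAT)** adipose tissue volumes, and the **VAT/ASAT ratio**,
from a person's outline: a pair of binary coronal and sagittal silhouettes
derived from volumetric body images. The VAT/ASAT ratio is a marker of
metabolically unhealthy fat distribution that is nearly independent of BMI
and waist circumference — a tape measure cannot tell whether central
obesity is visceral or subcutaneous, but the body outline carries shape
information that can.

The package is aimed at methods researchers in body-composition and
cardiometabolic epidemiology. Because the underlying imaging cohort is
access-controlled, `silfat` ships a synthetic body-phantom population with
labelled adipose compartments; every component is exercised end-to-end on
phantoms.

## What it implements

1. **Phantom cohort generator** — 3-D body volumes built from stacked
   elliptical cross-sections with VAT core / ASAT ring / GFAT shell labels;
   anthropometrics (height, weight, BMI, waist/hip by marching-squares
   contour perimeter, bioimpedance) and simulated prevalent/incident
   disease labels (logistic and exponential-hazard models per SD of
   exposure).
2. **Silhouette pipeline** — series merging, per-slice Otsu segmentation
   (largest 4-connected component, hole filling), orthogonal OR-projection,
   aspect correction, composition into the fixed 237 × 256 two-panel
   binary image.
3. **Multi-task convolutional regressor** — a compact conv trunk with four
   regression heads (VAT, ASAT, GFAT, ratio), trained with Adam on
   standardized targets under **nested cross-validation**: 5 outer
   partitions, models trained on 3, tested on 1, with unbiased predictions
   collected on the remaining validation partition; each outer model is a
   mean-ensemble of 3 inner cross-validation networks. For participant *i*
   with targets *y* and prediction *ŷ*, performance is reported as
   R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)² and MAE, with percentile-bootstrap 95% CIs
   (1000 resamples).
4. **Linear benchmarks** — sex-stratified OLS comparators on the shared
   folds (`BMI`: age+BMI; `Waist`: age+waist; `Anthro`: age + weight +
   height + BMI + waist + hip + WHR + 5 bioimpedance channels;
   `Silhouette`: age + the network prediction), and paired-bootstrap ΔR²
   comparisons.
5. **Disease associations** — OR/SD logistic and HR/SD Cox models
   (adjusted for age, centre, optionally BMI and waist), quintile
   gradients (Q1 / Q2–4 / Q5), and standardized prevalence within
   BMI × waist cells via g-computation.

## Worked example

A shape-driven phantom cohort (depot volumes are deterministic functions of
body shape), silhouettes, and the full nested-CV training run:

```r
library(silfat)

gen <- generate_cohort(2000, population_config(sigma_resid = 0), seed = 11)
X <- silhouette_matrix(gen$silhouettes)
Y <- as.matrix(gen$cohort[, c("VAT_L", "ASAT_L", "GFAT_L", "ratio")])

pred <- run_nested_cv(X, Y, gen$cohort$id, seed = 21, progress = TRUE)
#> outer model 1/5: test R2(VAT) = 0.925
#> ...
#> outer model 5/5: test R2(VAT) = 0.945

r2_mae(Y[, "VAT_L"], pred$VAT_pred)[["R2"]]    #> 0.9395117
r2_mae(Y[, "ASAT_L"], pred$ASAT_pred)[["R2"]]  #> 0.8726989
r2_mae(Y[, "GFAT_L"], pred$GFAT_pred)[["R2"]]  #> 0.962049
r2_mae(Y[, "ratio"], pred$ratio_pred)[["R2"]]  #> 0.7762714
```

Out-of-fold R² near 0.94 for VAT and lower for the ratio mirrors the
qualitative pattern of silhouette-based estimation: depot volumes are
easier than depot *ratios*. On this cohort the silhouette model beats the
combined anthropometric comparator for VAT (ΔR² > 0 with a bootstrap CI
excluding zero) because waist circumference is blind to the latent
fat-distribution axis while the outline is not — the package's desk-scale
analogue of the silhouette-vs-anthropometrics comparison. The whole run
takes about six minutes on one core (≈2.5 min cohort, ≈3.5 min training).

Disease associations on simulated labels:

```r
co <- gen$cohort
co$ratio_pred <- pred$ratio_pred
fit_prevalent(co, "t2d", "ratio_pred", adjustment = "bmi_waist")
```

returns the OR per sex-specific SD of predicted VAT/ASAT with Wald 95% CI.

A full demo (cohort → silhouettes → training → benchmark → associations →
markdown report) is available as `run_demo(out_dir, run_config(n = 250))`,
or from the shell via `inst/cli/silfat.R`.

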