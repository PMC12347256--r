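# fibroquant

Integrated, fully testable re-implementation of a diagnostic imaging
analysis for pulmonary hypertension (PH) in interstitial lung disease
(ILD): quantitative CT lung-texture segmentation, MRI-style right
ventricular (RV) volumetry and strain from contours, hemodynamic PH
labelling, and the incremental-diagnostic-value statistics that quantify
what adding RV function to CT fibrosis burden buys. It is aimed at
researchers who want the full analysis chain reproducible on synthetic
data with known ground truth — no patient images or tables are required.

## What it computes

**Lung texture (GHNC-style classifier).** Every lung pixel gets a feature
vector built from two Gaussian-weighted local histograms — of the CT
attenuation values and of the gradient-magnitude image — and is assigned to
one of six parenchymal classes (normal N, emphysema E, ground-glass G,
consolidation C, reticulation R, honeycombing H) by maximal normalized
correlation against per-class reference histograms built from template
patches. Class volumes are reported as percent of CT lung volume; the
*diseased lung area* is the sum of all non-normal fractions,
`100 − fraction(N)`.

**RV function.** Volumes by disk summation over cine contour stacks,
`V = Σ area_i × (thickness + gap)`; EF from the maximal (ED) and minimal
(ES) volume phases; global RV longitudinal strain from the open endocardial
arc length *L(t)*, `strain(t) = 100 (L(t) − L(ED)) / L(ED)`, with the peak
(most negative) value as the strain measure.

**Hemodynamics.** `PVR = (mPAP − PCWP)/CO` in Wood units (1 WU = 80
dyn·s·cm⁻⁵); PH ⇔ mPAP ≥ 20 mmHg and PVR ≥ 3 WU (inclusive bounds);
eligibility excludes PCWP > 15 mmHg.

**Diagnostics.** Mann–Whitney group comparisons (exact enumeration at small
n, tie/continuity-corrected normal otherwise); logistic model stacking;
AUC by the rank estimator with DeLong 95 % CIs and Youden cutpoints;
continuous NRI and IDI with seeded stratified-bootstrap CIs; quadrant
stratification of the cohort at the two marker thresholds.

**Synthetic data.** Texture phantoms (Voronoi-tiled elliptical lung, known
class map) and two-group cohorts (multivariate-normal features matching the
published PH / non-PH group statistics, hemodynamics consistent with the
group label by construction) make every stage testable.

## Worked example

```r
library(fibroquant)

# six well-separated texture classes -> phantom -> segment -> quantify
specs <- list(
  texture_class_spec("N", -900, 10), texture_class_spec("E", -700, 10),
  texture_class_spec("G", -500, 10), texture_class_spec("C", -300, 10),
  texture_class_spec("R", -100, 10), texture_class_spec("H",   50, 10))
ph   <- generate_phantom(128, 128, specs, layout_seed = 1)
tpl  <- generate_class_templates(specs, size = 21, seed = 2)
kern <- gaussian_kernel_spec(2.5, 11)
hs   <- histogram_spec(-1024, 100, 25)
refs <- build_reference_histograms(tpl, kern, hs)
lm   <- classify_image(ph$intensity, ph$lung_mask, refs, kern, hs)
phantom_accuracy(lm, ph, border_erosion = 5)
#> [1] 100

# cohort with the published group statistics -> incremental value
co <- generate_cohort(cohort_spec(seed = 7))
stepwise_combination(co, "diseased_area", c("rvesv", "rv_strain"),
                     n_boot = 200, seed = 3)[, c("model", "auc", "nri", "idi")]
#>                               model       auc       nri        idi
#> 1                     diseased_area 0.8403361        NA         NA
#> 2             diseased_area + rvesv 0.9225023 0.9579832 0.23705291
#> 3 diseased_area + rvesv + rv_strain 0.9477124 0.8011204 0.09208418
```

The accuracy is the percent of lung pixels classified to their true class
away from region borders; the table shows how the in-sample AUC grows as RV
end-systolic volume and RV strain are added to the CT fibrosis marker, with
the continuous NRI and IDI quantifying the reclassification gain of each
step (this simulated 72-subject cohort happens to discriminate a bit better
than average; across many seeds the medians sit near 0.80 → 0.85 → 0.88).

## Analysis workflow

The numbered drivers under `analysis/` run the full chain at scale and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # phantom + templates + 21/51 cohort
Rscript analysis/02_segment.R       # segmentation, fractions, overlay
Rscript analysis/03_cardiac.R       # EDV/ESV/EF/strain recovery
Rscript analysis/04_hemodynamics.R  # PVR + PH labels + eligibility
Rscript analysis/05_diagnostics.R   # group stats, ROC, NRI/IDI, quadrants
```

`run_pipeline()` performs the same stages from one YAML-serializable
configuration with a checksummed run manifest.

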