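---
title: "Methods: quantitative lung fibrosis, RV function, and incremental PH diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative lung fibrosis, RV function, and incremental PH diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and rationale

Pulmonary hypertension (PH) complicating interstitial lung disease (ILD) is
diagnosed invasively at right heart catheterization, but two imaging axes
carry most of the diagnostic signal: the extent of fibrotic lung on CT and
right-ventricular (RV) function on cardiac MRI. `fibroquant` implements an
integrated, fully synthetic-testable version of that analysis:

1. a six-class lung texture classifier (normal N, emphysema E, ground-glass
   opacity G, consolidation C, reticulation R, honeycombing H) driven by
   normalized correlation of Gaussian-weighted local histograms against
   per-class reference histograms, with volume fractions and the *diseased
   lung area* (100 % minus the normal fraction) as outputs;
2. RV volumetry by disk (area) summation over cine contour stacks and RV
   longitudinal strain from the endocardial arc length of four-chamber
   contours;
3. pulmonary vascular resistance, PVR = (mPAP − PCWP)/CO, and the
   hemodynamic PH rule mPAP ≥ 20 mmHg with PVR ≥ 3 Wood units;
4. the incremental-value statistics: Mann–Whitney group comparisons,
   logistic model stacking, ROC/AUC with DeLong intervals and Youden
   cutpoints, continuous net reclassification improvement (NRI), integrated
   discrimination improvement (IDI), and quadrant stratification.

No patient data ship with the package. Synthetic phantoms and cohorts with
known ground truth substitute for the images and the patient table, so every
stage is testable against either an analytic value or a brute-force oracle.

# Texture classification

## Model

For every lung pixel a feature vector is formed by concatenating two local
histograms: one of the CT attenuation values and one of the
gradient-magnitude ("differential") image. Each local histogram weights the
pixels of a square window by a truncated 2-D Gaussian and renormalizes to
unit mass; window parts falling outside the image are dropped before
renormalization, so border pixels remain well defined. Per-class reference
histograms are the averages of these local histograms over labeled template
patches, channel-normalized the same way. The pixel is assigned to the
class whose reference maximizes the Pearson-type normalized correlation
with its feature vector; exact ties resolve deterministically in the fixed
order N < E < G < C < R < H (so a fully degenerate input yields "normal").

## Parameters

* **Window / sigma** (`gaussian_kernel_spec`): default 51 px window,
  sigma 12.5 px. A "50-pixel neighborhood" admits several readings (radius,
  diameter, count); we take a window spanning ~50 px with sigma = window/4,
  and leave both configurable. Tests and small-scale analyses use smaller
  windows (9–15 px) purely to keep problem sizes desk-scale; the operations
  are scale-free.
* **Attenuation binning** (`histogram_spec`): default −1024 to 100 HU in
  25-HU bins (45 bins), covering lung parenchyma from air to soft tissue.
  Values outside the range clamp to the end bins. The differential channel
  may use its own binning; the pipeline default spans 0–281 HU in 6.25-HU
  bins, since gradient magnitudes concentrate near zero.
* **Feature combination**: the two channels are concatenated into one
  vector before a single correlation, the simplest faithful reading of
  "reference histograms from both original and differential images". Raw
  attenuation is not used as a separate feature beyond its histogram.

## Implementation notes

The per-pixel definition is the contract; the implementation evaluates it
for all pixels at once by per-bin separable convolution (the local
histogram mass of bin *b* at every pixel is the Gaussian smoothing of the
indicator image of bin *b*, normalized by the smoothed mask), which is
mathematically identical and keeps a 256×256 slice with a 51×51 kernel in
well under a second. The test suite verifies the equivalence against a
literal per-pixel reimplementation on small random images, label for label.

Volume fractions are pixel counts over the lung mask scaled to percent of
the CT lung volume (CTLV); by construction they sum to 100 and the diseased
area equals 100 minus the normal fraction exactly. Overlays use the
conventional palette: normal pink, emphysema dark blue, GGO orange,
reticulation light blue, honeycombing yellow; consolidation, which has no
color in that convention, renders firebrick red.

# Synthetic phantoms

Phantoms tile an elliptical "lung" with Voronoi cells seeded at random
interior points, classes assigned round-robin over the seeds so that all
six classes are present; layouts leaving any class under 1 % of the mask
are redrawn deterministically. Per class, intensities are the class mean
plus an optional texture (2-D sinusoid for honeycomb-like cells, 1-D
streaks for reticulation) plus Gaussian noise. Default means (N −850,
E −950, G −650, C −100, R −500, H −750 HU; common SD 40 HU) mimic real
relative attenuations, making the default classification problem
non-trivial; tests that assert ≥ 95 % accuracy use explicitly
well-separated variants (≥ 10 SD between adjacent means), which is the
regime the accuracy claim refers to. The phantom does **not** emulate
scanner noise spectra, 3-D fibrosis morphology, respiratory motion, or
airway/vessel structures, so passing accuracy tests demonstrates the
correctness of the classifier machinery, not clinical segmentation
performance on real CT. Lung masking itself is an input, not an output.

# Synthetic cohorts

Cohorts are drawn per group (default 21 PH / 51 non-PH) from a multivariate
normal over eight features (RV strain, RVESV, diseased area, GGO,
honeycomb, reticulation, emphysema, consolidation) with the study-condition
group means and SDs, then clipped: percentages to [0, 100], strain to ≤ 0.
Clipping rather than rejection preserves seed determinism; its bias is
negligible for features several SDs inside their range but measurably
contracts the SD of markers sitting ~2 SD above zero (GGO, honeycomb,
consolidation), which the tests acknowledge by checking SD fidelity only on
effectively unclipped features. The default correlation matrix is the
identity: the source analysis reports no feature correlations, and
independence is the neutral choice; any symmetric positive-definite matrix
can be supplied.

Hemodynamics are simulated conditionally on group so the labels are exact:
PH subjects draw mPAP ~ N(32, 6) truncated ≥ 20 and PVR ~ N(5, 1.5)
truncated ≥ 3 WU, with CO back-computed from the PVR identity; non-PH
subjects draw mPAP ~ N(16, 3) truncated < 20. All wedge pressures stay
≤ 15 mmHg, matching the eligibility rule. No study-reported hemodynamic
summaries exist to calibrate against, so these parameters are plausible
clinical values chosen once and documented here.

# Cardiac measures

Volumes follow Simpson's principle: contour areas (shoelace formula) summed
over slices times the slice increment. End-diastole is the maximal-volume
phase and end-systole the minimal (no ECG in the contour representation);
ties take the earlier phase. Strain uses the open endocardial polyline —
the valve-plane closing segment is excluded — resampled to 64 equally
spaced points for correspondence and noise robustness; strain(t) is the
percent change of summed arc length relative to end-diastole, and the peak
is the most negative value. Strain is *global* RV longitudinal strain, not
free-wall-only strain. Trabeculae exclusion is the contour provider's
responsibility.

Two generators support recovery tests: a contracting ellipsoid stack with
prescribed EDV/ESV (volumes recovered within 2 % at 1-mm slices; the
residual is disk-summation discretization plus the 128-gon area deficit)
and a shortening four-chamber contour with prescribed peak strain
(recovered to numerical precision, since uniform scaling commutes with
resampling). Volumes and strain come from separate synthetic cines by
design — mirroring the source analysis, where volumes come from cine
stacks and strain from four-chamber feature tracking — because one
isotropic contraction cannot prescribe EF and strain independently.

# Hemodynamics

PVR is returned in Wood units with the exact ×80 conversion to
dyn·s·cm⁻⁵. Both PH boundaries are inclusive (mPAP = 20 and PVR = 3
classify as PH); the newer PVR > 2 WU definition is available as a
configuration (`pvr_cutoff = 2, pvr_inclusive = FALSE`). A negative
transpulmonary gradient is allowed but warned about. The eligibility
filter removes PCWP > 15 mmHg strictly (15 is retained) and reports the
count removed.

# Diagnostic statistics

* **Mann–Whitney**: U is oriented pairwise concordance (ties ½). With both
  groups ≤ 10 the two-sided p comes from exact enumeration of the
  permutation distribution over group assignments of midranks — valid under
  ties, where the textbook exact distribution is not; otherwise the normal
  approximation with tie and continuity corrections is used.
* **Logistic models**: binomial maximum likelihood by IRLS (tolerance 1e-8,
  ≤ 100 iterations) via the standard glm machinery, wrapped with explicit
  separation detection (boundary fitted probabilities or exploding
  standardized coefficients); separated fits are flagged, never silently
  reported.
* **ROC/AUC**: the rank (Mann–Whitney) estimator with midrank tie handling;
  DeLong placement-value variance for the 95 % CI and the p-value against
  AUC 0.5, computed from ranks in O(n log n). The Youden cutpoint maximizes
  sensitivity + specificity − 1 over observed values with the *lower*
  threshold on ties; a direction flag orients markers so "larger = more
  disease-like" (RV strain uses `>`: less negative strain is abnormal),
  with thresholds reported on the original scale.
* **NRI/IDI**: continuous (category-free) NRI with ties counting toward
  neither direction; IDI as the difference in discrimination slopes.
  Confidence intervals are percentile intervals from a seeded, stratified
  (per-class) bootstrap, 2000 resamples by default; p-values are normal
  approximations from the bootstrap SE. The source analysis does not state
  its CI method; the bootstrap is the assumption-light default, and
  stratification keeps both classes present in every resample. In-sample
  continuous NRI is known to be slightly positively biased for nested
  models; the tests treat the noise-augmentation null accordingly
  (majority-of-seeds coverage rather than a single draw).
* **Quadrant analysis**: membership by (x ≥ x-threshold) × (y ≥
  y-threshold) with boundaries on the abnormal side; empty quadrants report
  no prevalence rather than 0.
* No multiple-testing adjustment is applied (matching the source analysis);
  α = 0.05 two-sided throughout.

Categorical NRI is deliberately not implemented — the analysis this package
reproduces uses only the continuous form.

# End-to-end pipeline and problem sizes

`run_pipeline()` chains simulate → segment → quantify → cardiac →
hemodynamics → diagnostics from one YAML-serializable configuration, with
one global seed fanned out per stage, stage-tagged logging and abort
messages, and a manifest listing every output file with its MD5 checksum;
reruns of the same configuration are bit-identical for all outputs. The
numbered scripts under `analysis/` run the same stages as a narrative
workflow at full scale (256×256 phantom, 51×51 kernel).

Default problem sizes used by the tests and the acceptance script — a
160×160 or smaller phantom with a 9–15 px kernel, cohorts of 21/51 with
100 simulation replicates, 500–2000 bootstrap resamples, and a single 10⁵
binormal AUC check — were chosen so the whole suite completes in a few
minutes on one CPU while keeping every statistical check comfortably
powered.

# Known limitations

* The classifier is 2-D slice-wise; 3-D texture features and subpleural
  honeycomb quantification are out of scope.
* Reference templates are user-supplied (or synthetic); the package does
  not ship population-derived reference classes.
* The cohort generator reproduces first and second moments per group, not
  the full joint distribution of real ILD cohorts; diagnostic statistics on
  synthetic cohorts show directional, not numeric, agreement with the
  source analysis.
* In-sample AUC/NRI/IDI are optimistic relative to external validation; no
  cross-validation is implemented.
* Strain is global RV longitudinal strain from contours; image-based
  feature tracking is not modelled.
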