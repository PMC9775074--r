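---
title: "Measuring glymphatic function with the DTI-ALPS index: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring glymphatic function with the DTI-ALPS index: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpskit)
```

## The scientific problem

The glymphatic system clears metabolic waste from the brain by exchanging
cerebrospinal and interstitial fluid through the perivascular spaces. Its
function cannot be observed directly without invasive contrast injection,
but diffusion MRI offers a proxy: beside the body of the lateral ventricle,
three tissue orientations are mutually perpendicular — projection fibers
run cranio-caudally (the z axis), association fibers (superior longitudinal
fasciculus) run anterior-posteriorly (y), and the perivascular spaces of
the medullary veins run left-right (x). Water diffusivity measured *along
x* in those two fiber regions is therefore dominated by perivascular
transport rather than by the fibers themselves, and the **ALPS index**

$$\mathrm{ALPS} = \frac{\operatorname{mean}(D_{xx}^{\mathrm{proj}},\,
D_{xx}^{\mathrm{asso}})}{\operatorname{mean}(D_{yy}^{\mathrm{proj}},\,
D_{zz}^{\mathrm{asso}})}$$

is used as a dimensionless measure of glymphatic transport efficiency.
Values near 1 indicate no preferential perivascular diffusion; healthy
adults typically measure around 1.5-1.8. In cerebral small vessel disease
(CSVD), white-matter hyperintensities (WMH), lacunes, microbleeds and
enlarged perivascular spaces accompany cognitive decline, and a central
question is whether reduced glymphatic function *mediates* the association
between WMH burden and memory impairment. This package implements the full
analysis chain: diffusion tensor fitting, ALPS measurement,
neuropsychological scoring, the four-group statistics battery, and a
bootstrap mediation model — together with a synthetic-data module that
generates imaging phantoms and cohort tables with exactly the structure
the analysis assumes, so every stage is testable without patient data.

## The diffusion model and tensor fit

Diffusion-weighted signals follow the monoexponential tensor model
$S_i = S_0 \exp(-b_i\, g_i^{\mathsf T} D\, g_i)$ with $D$ a symmetric
positive-definite 3×3 tensor (mm²/s). `fit_tensor()` solves the classic
log-linear ordinary least-squares problem per voxel: with at least six
non-collinear directions plus a b0 frame, $\ln(S_i/S_0)$ is linear in the
six unique tensor components. Choices made here:

* **Ordinary (unweighted) least squares**, matching the long-standing
  default of clinical tensor-fitting tools. Weighted or nonlinear fits
  reduce noise-induced bias slightly but change no conclusions at the SNR
  this pipeline targets.
* **Multiple b0 frames are averaged** before the log-ratio, the
  conventional treatment.
* **Voxels with any non-positive signal are masked out**, never fitted;
  negative eigenvalues or negative diagonal elements produced by noise are
  clamped to zero in the derived maps, with a clamp counter on the
  returned field (`$n_clamped`). The raw fitted tensors are kept unclamped.
* The axis convention is fixed and explicit: x = left-right,
  y = anterior-posterior, z = cranio-caudal. The maps `dxx`, `dyy`, `dzz`
  are tensor *diagonal elements in that frame*, not eigenvalues — the
  distinction the ALPS construction depends on. A missing axis convention
  is a hard error, never a silent assumption.

Fractional anisotropy uses the standard eigenvalue formula and is exactly
rotation-invariant; the direction-encoded color map follows the
radiological convention (red = x, green = y, blue = z), each channel
|principal direction component| × FA.

## ROI placement and the ALPS measurement

The conventional ALPS ROI "sphere of 12 voxels" is geometrically ambiguous
on a lattice: no generic radius contains exactly 12 voxels. `sphere_roi()`
resolves it deterministically — voxels are ordered by squared Euclidean
distance from the center with ties broken lexicographically by (x, y, z)
index, and the first n = 12 are taken. The count is configurable; an ROI
crossing the volume boundary is an error, never a silent truncation.

`measure_alps()` averages `dxx` and `dyy` over the projection ROI and
`dxx` and `dzz` over the association ROI and forms the ratio. Because a
diffuse diffusivity elevation (the WMH effect) multiplies numerator and
denominator alike, the index is exactly invariant under global tensor
scaling — a property the test suite asserts to machine precision. Manual
ROI centers are the primary interface, mirroring practice, where ROIs are
drawn by a radiologist; `suggest_roi_centers()` is an opt-in convenience
that maximizes the blue channel for the projection ROI and then the green
channel at the same x and z coordinates ("parallel" placement in the same
axial plane, shifted anterior-posteriorly). Only the left-hemisphere index
is computed by default, matching the clinical convention for this
measurement; phantom work may measure anywhere.

## Cohort scoring

Ten neuropsychological tests map onto five domains, two tests each:
episodic memory (WMS visual reproduction delayed recall, AVLT delayed
recall), language (Boston Naming, category fluency), processing speed
(TMT-A, Stroop B), executive function (TMT-B, Stroop C) and visuospatial
function (clock drawing, visual reproduction). Timed tests are inverted
before standardization so larger always means better; the default
inversion is **negation** rather than the reciprocal — both reverse the
ranking, negation keeps z magnitudes symmetric (a config switch selects
the reciprocal). Each test is z-transformed against a reference
population and each domain composite is the mean of exactly its two
constituent z-scores; missing constituents propagate, nothing is imputed.

The z reference defaults to the **whole analyzed sample**. The alternative
(normal controls only) is available, but whole-sample referencing is the
reading consistent with published four-group composite tables in which the
control group's composites are not centered at zero.

Diagnostic classification applies education-adjusted screening rules:
MMSE dementia cutoffs ≤17 / ≤20 / ≤24 for 0, 1-6 and >6 years of
education; MoCA normal-cognition cutoffs >13 / >19 / >24 for 0, 1-6 and
7-12 years. No cutoff is published for more than 12 years of education;
the 7-12-year value is carried upward and a message notes the extension on
every use. Dementia requires CDR ≥ 1; MCI requires CDR = 0.5 and ADL = 8;
normal cognition requires CDR = 0 and ADL = 8. Records matching no rule
are returned as `unclassifiable`, never coerced. Marker transforms use
log10(x + 1) — base 10 with a +1 offset because the lacune and microbleed
counts include zeros — and EPVS is coded 1/0.

## Group statistics

Continuous variables are gated per group by Shapiro-Wilk at α = 0.05
(the conventional choice where a normality test is not otherwise named):
normal variables are summarized mean ± SD and compared by one-way ANOVA or
a covariate-adjusted linear model; non-normal ones are summarized
median (IQR) and compared by Kruskal-Wallis. Categorical variables use the
Pearson chi-square **without continuity correction** — the form that
reproduces published four-group table statistics exactly from their
printed counts — with cells of expected count < 5 flagged; the exact test
is restricted to 2×2 tables. `anova_from_summary()` recovers the exact
fixed-effects ANOVA from per-group n/mean/sd, which lets printed cohort
tables be re-tested without raw data. Post hoc contrasts of
covariate-adjusted group means use the Bonferroni multiplier
m = k(k−1)/2 = 6 for four groups, the standard reading of "Bonferroni
corrected" pairwise comparisons. Partial correlation is the Pearson
correlation of least-squares residuals after regressing both variables on
the covariates (plus intercept), tested on n − 2 − q degrees of freedom.

## The mediation model

`fit_mediation()` is the covariate-adjusted single-mediator model in its
three-regression form: `mediator ~ exposure + covariates` (path a),
`outcome ~ exposure + mediator + covariates` (paths b and c′) and
`outcome ~ exposure + covariates` (total effect c), all coefficients
non-standardized, with the identity c = c′ + a·b holding exactly for OLS
with shared covariates. The indirect effect a·b gets a case-resampling
bootstrap interval: subjects are resampled with replacement k times
(default 5000) and the a and b paths refit. Both the **bias-corrected**
interval (the default of the established macro-based implementations,
and the reading adopted for "bias and corrected" intervals) and the plain
percentile interval are provided; they coincide when the bootstrap
distribution's median equals the point estimate. Degenerate (rank
deficient) resamples are redrawn and counted. Mediation is declared
present iff the interval excludes zero. The exposure enters on the
log-transformed WMH scale by default, consistent with the marker
transformation applied before analysis.

One identifiability point is worth recording: a *fully deterministic*
chain (zero mediator residual) makes the outcome design singular — the
mediator then lies exactly in the span of exposure and covariates — and
the fit correctly refuses it. "Noiseless" recovery is therefore tested in
the identifiable limit: a deterministic outcome equation recovers b and c′
exactly, and vanishing mediator noise recovers all paths to the
corresponding precision.

## What the synthetic data emulate — and what they do not

`phantom_spec()` builds the perpendicular three-tissue geometry at the
heart of the measurement: a projection block (base tensor
diag(0.6, 0.6, 1.7)×10⁻³ mm²/s, principal axis z), an association block
(diag(0.6, 1.7, 0.6)×10⁻³, principal axis y) sharing the same x and z
extent on the phantom's axial slices, an isotropic surround and
background. The perivascular component is an additive left-right
diffusivity `pvs_axis_boost` in both fiber regions; its default
4.56×10⁻⁴ mm²/s puts the noiseless index at 1.76, the healthy-range
calibration value. WMH load is a global multiplicative factor `wmh_scale`
(≥ 1), expressing the view that hyperintensities elevate diffusivity in
all directions — which is exactly what the ALPS ratio cancels. Simulated
acquisitions use one b0 plus 32 golden-angle directions at
b = 1000 s/mm², 2×2×2.5 mm voxels, and Rician noise (Gaussian noise on
the real and imaginary channels before the magnitude), the standard model
for magnitude MRI. No acquisition noise level is published for the study
conditions this emulates; the default `noise_sigma = 1/30` (SNR 30
relative to b0) is a typical clinical DTI figure and is the level the
robustness properties are tested at.

`cohort_spec()` generates the four-group cohort (52 controls; 137 CSVD
patients split 56 / 52 / 29 into cognitively normal, MCI and dementia)
with group means and SDs for demographics, screening scores, the ALPS
index and the five domain composites taken from the published cohort
tables as calibration defaults; WMH volume is log-normal on the
log10(x+1) scale, lacune and microbleed counts are zero-inflated Poisson,
EPVS is Bernoulli. The mediation chain is generated on the transformed
scales with defaults a = −0.19, b = 0.814, c′ = −0.05, chosen so the
implied indirect effect (≈ −0.155) and the WMH-ALPS correlation (≈ −0.45)
match the published estimates used as calibration anchors. Residual SDs
(ALPS 0.17, memory 0.55) complete the group SDs to their table values.
Screening scores are redrawn (up to 30 times) for subjects whose draw
contradicts their intended diagnostic label; the survivors are flagged
`label_consistent = FALSE`, never relabelled. This conditioning slightly
truncates the MMSE/MoCA score distributions; the moment-recovery
guarantees in the test suite therefore apply to the unconditioned fields
(age, education, ALPS).

What the generator does **not** emulate: anatomically realistic
templates, registration or motion artifacts, lesion-mask images (WMH
enters as a scalar volume), item-level test scoring, and missing-data
patterns. Passing tests demonstrate that the pipeline's arithmetic,
identities and interval procedures behave correctly under the assumed
statistical structure — not that the structure itself describes any
particular clinical population. Under the default calibration the
MCI-group mediation (n = 52) yields an interval that only borderline
excludes zero across realizations, which is the expected behavior at this
sample size and noise level.

## Numerical choices and problem sizes

Tolerances asserted by the test suite: noiseless tensor round-trips to
1e-12 relative error (measured ≈ 5×10⁻¹⁶); FA rotation invariance to
1e-9; summary-statistic ANOVA against the raw decomposition to 1e-10;
partial correlation against explicit residualization to 1e-12; the
mediation decomposition to 1e-10. Simulation-based checks run at fixed
seeds: interval coverage over 1,000 generated MCI-sized cohorts at
k = 1000 (accepted at 93-97%), type-I error of ANOVA, Kruskal-Wallis and
partial correlation over 10,000 null replicates (accepted at
0.05 ± 0.007), and ALPS bias at SNR 30 over 200 noisy phantom
realizations (accepted below 5%). These sizes keep each property
statistically meaningful while the whole suite completes in a few
minutes; the acceptance script uses 100 noisy realizations and k = 5000
bootstrap replicates for its reported quantities.

Tie-breaks are deterministic everywhere randomness is not intended: ROI
membership (distance then lexicographic), ROI suggestion (lowest
lexicographic voxel among maxima), and bootstrap resampling (explicit
seeds, restored RNG state). All generator and bootstrap seeds are recorded
in fixture manifests and reports.

## Known limitations

* Only the single-slab, left-side ALPS variant is implemented; along-tract
  or whole-brain variants are out of scope.
* The tensor fit is single-shell DTI; multi-compartment models (free
  water, DKI) that would sharpen the perivascular interpretation are not
  included.
* The exact test is 2×2 only; four-group categorical tables with sparse
  cells are handled by the chi-square with a low-expected-count flag.
* The classification rules implement one published education-adjusted
  scheme; sites using different norms must re-map before classifying.
* Mediation is single-mediator with complete-case handling; multiple
  mediators, moderated mediation and sensitivity analyses for unmeasured
  confounding are out of scope.
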