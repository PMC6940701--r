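---
title: "Methods: the D50 progression model and permutation-based morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the D50 progression model and permutation-based morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(d50vbm)
```

## The disease-progression model

Amyotrophic lateral sclerosis (ALS) is clinically tracked with the revised
ALS Functional Rating Scale (ALSFRS-R), a 12-item questionnaire summing to
48 (full function) down to 0. Its raw slope, the progression rate
PR = (48 − score)/months-since-onset, assumes linear decline and is noisy
early and late in the disease. This package instead models each patient's
decline as a symmetric sigmoidal transition from full health to complete
functional loss,

$$F(t) = \frac{48}{1 + \exp\{(t - D50)/s\}},$$

with two parameters: *D50*, the number of months from symptom onset until
half of the functionality is lost (F = 24), and a time-scale *s* (months)
governing how steep the transition is. D50 summarises overall disease
aggressiveness independently of when a patient happens to be assessed.

From a fitted curve and any reference time $t_{\mathrm{ref}}$ (typically the
MRI acquisition date) the model yields:

* **rD50** $= t_{\mathrm{ref}} / (2\,D50)$ — unitless disease covered:
  0 at onset, 0.5 at half functionality; open-ended above.
* **cFS** $= F(t_{\mathrm{ref}})$ — calculated functional state in
  ALSFRS-R points.
* **cFL** $= -F'(t_{\mathrm{ref}})$ — calculated functional loss rate in
  points lost per month; at the midpoint this equals $12/s$.
* **Phase** — I for rD50 in [0, 0.25), II for [0.25, 0.5), III/IV (pooled)
  for rD50 ≥ 0.5; the intervals are half-open with inclusive lower bounds.
* **Aggressiveness class** — high if D50 < 30 months, low otherwise.

### Fitting

`fit_d50()` minimises the residual sum of squares by bounded nonlinear least
squares (L-BFGS-B) with D50 ∈ (0.1, 1200] and $s$ ∈ (0.1, 600] months, a
deterministic two-point multi-start (PR-extrapolation to the midpoint, and
the last observation time), tolerance 1e-8 and at most 500 iterations.
Integer scores are fitted as reals. Two numerical choices deserve note:

* **Onset anchor.** By default a pseudo-observation (t = 0, score = 48) is
  appended — the model's premise of full function at symptom onset — which
  makes single-visit series fittable. Because $F(0) < 48$ for any finite
  parameters, the anchor carries a small residual of its own; on noiseless
  synthetic series it biases the optimum slightly, so the exact
  parameter-recovery checks in the test suite disable it via
  `d50_fit_control(anchor_onset = FALSE)`. With real, noisy series the
  anchor is a stabiliser, not a bias of practical consequence.
* **Degeneracy.** A series whose observations (including the anchor) all sit
  at the plateau leaves D50 unidentifiable; the fit raises an error rather
  than returning an arbitrary large value. Optimizer failure is reported via
  `converged = FALSE`, never silently.

### Staging a cohort

`build_cohort_table()` evaluates descriptors at the MRI date, classifies
phase and aggressiveness, and natural-log transforms D50, rD50, cFS and cFL
before they enter any design matrix (to approximate normality). The
ALSFRS-R score "at MRI" is the observation closest in time, accepted only
within 100 days (at 30.4375 days/month); an equidistant tie is broken toward
the earlier, pre-scan visit as the conservative choice. A patient at exactly
rD50 = 0 would have no finite log; the package raises an error there instead
of imputing, since a patient scanned at symptom onset is outside the model's
intended use.

## The synthetic cohort

No patient data ship with the package; `sample_cohort()` generates a
ground-truth cohort whose structure matches a typical cross-sectional ALS
imaging cohort:

* D50 lognormal with median 30 months and sdlog 0.6, truncated to [8, 176]
  months — empirical mean ≈ 36 months with SD ≈ 25, matching the reported
  spread of D50 in such cohorts.
* The sigmoid time-scale is tied to D50 (ratio 4:1) with mild lognormal
  jitter (sdlog 0.15), so fast progressors also decline steeply; the jitter
  keeps the two parameters separately identifiable.
* Onset type bulbar with probability 0.28; patient ages normal 60 ± 11.5
  years and controls 54 ± 12.8, clipped to [18, 90]; TIV normal 1450 ± 120
  mL.
* The disease covered at MRI is drawn as rD50 ~ truncated normal
  0.27 ± 0.13 on [0.02, 0.75] and converted to an MRI date via
  $t = 2\,\mathrm{rD50}\,D50$. This reproduces the canonical phase
  occupancy (roughly 40% Phase I, 56% Phase II, few percent Phase III/IV)
  and guarantees all phases occur in large cohorts.
* Visits are quarterly starting at the MRI date (4 by default) — a
  plausible clinic follow-up schedule; visit noise is i.i.d. discrete
  uniform on {−2, …, 2} points before rounding and clipping to [0, 48].
  No published per-visit noise magnitude exists; ±2 points is an assumption
  exposed in `cohort_params()`.

All randomness flows from one master seed through deterministic per-subject
seeds, so a cohort can be extended without reshuffling existing subjects.

Under these defaults, 200 simulated patients with 4 visits yield a median
relative D50 recovery error well under 15% (computed in the test suite).
What the generator does **not** emulate: dropout and death censoring,
sub-score structure, floor effects from respiratory-onset phenotypes, or
correlation between visit noise and disease severity. A green test
establishes that the pipeline recovers what was planted under the stated
noise model — not that the model is unbiased on real registry data.

## Synthetic morphometry

Real voxel-based morphometry starts from segmented, spatially normalised
gray-matter (GM) and white-matter (WM) probability maps. The package
replaces acquisition and segmentation with a phantom: per tissue, a smooth
random blob template on a 32×32×32 grid of 4 mm voxels (a desk-scale
stand-in for MNI space), values in [0.25, 0.85]. Planted effects multiply
the template by $\prod_r (1 - \beta_r x_{ir})$ inside disjoint box regions
("frontal" and "temporal" GM, a WM "tract"), where $x_{ir}$ is the
subject's value of the driving predictor and $\beta_r$ the fractional
density reduction per unit predictor (default 0.1). In the full pipeline GM
loss scales with disease covered (rD50) and WM loss with the
high-aggressiveness indicator, mirroring the phase- and
aggressiveness-linked findings the field reports. Gaussian voxel noise
(SD 0.05) is added and values are clipped to [0, 1].

Preprocessing mirrors the standard pipeline: separable Gaussian smoothing
with an 8 mm FWHM kernel (σ = FWHM/2.355 per axis in voxel units,
edge-inclusive reflective boundaries — a symmetric, mean-preserving
operator), and implicit masking at an absolute density threshold of 0.2.
The masking rule is applied to the cohort **mean** image rather than
per-image; the per-image variant would make the analysis mask depend on
noise realisations, and the original toolbox's behaviour is not
recoverable, so the deterministic variant was chosen and is noted here as a
deviation. Volumes can be written and read as single-file NIfTI-1
(float32); the reader/writer is intentionally minimal since no NIfTI
package is available in the supported dependency set.

## The statistical engine

### Voxel-wise GLM

`fit_glm_tmap()` fits an ordinary least-squares model with a common
subjects × predictors design at every in-mask voxel and returns the
contrast t-map $t = c^\top\hat\beta / \sqrt{\hat\sigma^2\,c^\top(X^\top
X)^{-1}c}$ with $n - \mathrm{rank}(X)$ degrees of freedom. ANCOVA-style
contrasts are expressed as an intercept, a group indicator and nuisance
columns (age, sex, TIV, onset type, log-descriptors as appropriate).
Rank-deficient designs fail loudly, naming the collinear columns.

### TFCE

Threshold-free cluster enhancement integrates cluster extent and height
across all thresholds:
$\mathrm{TFCE}(p) = \int_0^{h_p} e_p(h)^E\,h^H\,dh$ with the field-standard
exponents H = 2, E = 0.5 and 26-neighbour connectivity (all configurable).
The implementation discretises the integral over bins of width `dh`
(default: max statistic / 100): the component size $e_p$ is sampled once
per bin at its midpoint with an incremental union-find (thresholds
processed high to low), while the $h^H$ factor is integrated exactly within
each bin and the voxel's own top bin is truncated at its statistic value. A
plain Riemann sum drifts by order $dh/h$ at each voxel's own height (about
1% at the default step); the bin-exact form makes results stable under `dh`
refinement (halving `dh` moves values by well under 0.5%), which matters
because the permutation null and the observed map must be enhanced on an
identical scale. Only the positive support is enhanced; decreases and
increases are tested as two separate one-sided analyses, matching how
morphometry studies report them.

### Permutation FWE

`permutation_fwe()` implements the Freedman–Lane scheme: nuisance columns
(zero contrast weight, including the intercept) are regressed out, the
residuals row-permuted, the nuisance fit added back, and the full model
refitted; the maximum in-mask TFCE per permutation forms the null
distribution of the family-wise maximum. P-values use the add-one
convention $p = (1 + \#\{\max^{(b)} \ge \mathrm{TFCE}_{\mathrm{obs}}\}) /
(n_{\mathrm{perm}} + 1)$, so no p can be zero and the smallest attainable
p is $1/(n_{\mathrm{perm}}+1)$. Runs are deterministic under a seed. A
requested α that the permutation count cannot resolve triggers a warning
(α = 0.001 needs at least 999 permutations; note that significance is the
strict inequality p < α, so comfortably exceeding that bound — e.g. 1999
permutations — is advisable). Group contrasts use α = 0.001 FWE;
descriptor regressions use α = 0.05 FWE with Bonferroni adjustment over
the two regressions sharing a tissue family, i.e. an effective 0.025.

`masked_regression()` restricts a descriptor regression to the significant
clusters of a prior case-control contrast, the standard small-volume
practice for follow-up correlations. `extract_clusters()` reports connected
components of {p < α} sorted by size, ties broken by peak TFCE and then
lexicographic peak coordinate, so cluster tables are reproducible
byte-for-byte.

### Calibration

The test suite verifies, under a fixed seed, that the family-wise
false-positive rate of the whole TFCE + permutation stack on pure-noise
two-group data (16 + 16 subjects, 16³ grid, 500 permutations, 200
replicates) lies within binomial error of the nominal 5%, and that a
planted 10% WM density reduction in the high-aggressiveness group of a
simulated 85-patient cohort is recovered at α = 0.001 with no spurious
clusters disjoint from the planted region.

## Presets and pipeline

`analysis_presets()` encodes the study designs: case-control GM/WM,
bulbar vs limb onset, Phase I vs Phase II (nuisance: onset type, age, sex,
TIV, log D50), high vs low aggressiveness (nuisance: onset type, age, sex,
TIV, log rD50), and the four descriptor regressions (rD50, cFS in GM and
WM; D50, cFL in WM; nuisance TIV). The rule: onset type, D50, rD50, age,
sex and TIV serve as nuisance covariates whenever they are not the primary
read-out. `run_pipeline()` chains simulation, fitting, staging, volume
generation and the configured presets into a run directory containing the
clinical CSV, the staged cohort table, cluster tables, NIfTI statistic maps,
a JSON config snapshot and a log; identical config and seed give identical
outputs. Config is JSON rather than YAML because the supported dependency
set has no YAML parser; the content is the same flat key-value snapshot.

## Known limitations

* The sigmoid is symmetric with fixed plateaus 48 and 0; real trajectories
  can be asymmetric or plateau above zero. The functional form is
  configurable in one place (`d50_fit_control(max_score = )` for the
  plateau) but asymmetric variants are out of scope.
* Phase III vs IV are pooled, as rD50 alone cannot separate them.
* The slope parameter's admissible range is an engineering choice; no
  published value constrains it.
* Permutations assume full exchangeability after nuisance residualisation;
  exchangeability blocks and variance smoothing are not implemented.
* Cluster anatomy is synthetic: box regions on a blob template. Findings on
  the phantom validate the machinery, not anatomical claims.
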