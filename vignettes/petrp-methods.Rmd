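---
title: "Methods: pre-treatment FDG-PET lung biomarkers and pneumonitis risk"
author: "petrp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-treatment FDG-PET lung biomarkers and pneumonitis risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Radiation pneumonitis (RP) is an inflammatory reaction of lung tissue to
thoracic radiotherapy, graded 0–5 on the CTCAE scale; grade ≥ 2 ("symptomatic")
is the clinically relevant endpoint.  A patient's baseline pulmonary
inflammation is visible on the staging FDG-PET as diffusely elevated uptake,
and the upper tail of the lung standard-uptake-value (SUV) distribution — in
particular its 95th percentile, SUV95 — is a candidate pre-treatment biomarker
of RP risk.  `petrp` implements the whole quantification-and-analysis chain:

1. **SUV conversion.** Voxelwise
   `SUV = activity (Bq/mL) × body weight (g) / (injected dose (Bq) ×
   2^(−t/T½))`, with `t` the injection-to-scan delay and `T½ = 109.771` min
   for ¹⁸F.  The decay correction is applied explicitly and logged; volumes
   already in SUV are never rescaled (converting a `PET_SUV` volume is an
   error by contract).
2. **Lung segmentation.** The lung region of interest (ROI) is obtained from
   the CT alone: Otsu's threshold on the HU histogram clipped to
   [−1000, 200] separates the air/lung modes from soft tissue (fallback
   −400 HU, manual override available); components touching the lateral
   image border (exterior air) are discarded; the two largest 26-connected
   components are kept and closed with a 2-voxel ball to re-absorb vessels.
   The central airway is removed by 6-connected region growing from the most
   superior sub-−950-HU cluster in the medial third of the axial plane,
   dilated by one voxel.  Artifact regions — cardiac/tumor PET spill-over
   and diaphragm attenuation cold-spots — enter as *exclusion masks*, i.e.
   file inputs reproducing the study's manual contouring step as data.
3. **Biomarkers.** Over the final ROI the panel mean, SD (n − 1 denominator),
   maximum and 80th/90th/95th percentiles is computed for SUV and for HU.
   The percentile is linear interpolation between order statistics at rank
   `1 + (p/100)(n − 1)` (the type-7 estimator); the estimator type is a
   configuration knob for sensitivity checks only.
4. **Dosimetry.** Mean lung dose and Vx = percent of ROI volume receiving
   *strictly more than* x Gy/CGE for x ∈ {5, 10, 20, 30}; proton doses are
   converted to Cobalt Gray Equivalents once by a constant RBE of 1.1.
5. **Outcome statistics.** Chi-squared (Yates-corrected on 2 × 2) and
   Mann–Whitney association tests; univariate logistic panels; Holm
   step-down over the six SUV predictors; backward-AIC multiple logistic
   regression with Wald tests, odds ratios `exp(β)` with
   `exp(β ± 1.96·SE)` intervals and Nagelkerke R²; ROC with DeLong variance
   and the Youden cutpoint; depth-2 Gini recursive partitioning on SUV95 and
   V30; Kaplan–Meier SUV95 terciles; Cox proportional hazards with Efron tie
   handling; and Bland–Altman inter-reader limits of agreement from a
   one-way ANOVA.

## Synthetic data: what it emulates and what it does not

No patient images or records ship with the package.  Two generators provide
ground-truthed substitutes.

**Thoracic phantom** (`generate_phantom`).  Two ellipsoidal lungs (−800 HU)
sit in a soft-tissue elliptic cylinder (+40 HU) surrounded by air
(−1000 HU); a branching central airway (−1000 HU) is kept one voxel clear of
the lungs so connected-component analysis can separate them.  Lung PET
voxels are drawn i.i.d. from a configurable marginal distribution (default:
lognormal with designed 95th percentile 1.2 and log-SD 0.25, matching the
magnitude of clinical lung-SUV distributions).  The three artifact classes
are switchable:

* *cardiac spill-over* — a high-uptake mediastinal sphere whose activity is
  blurred by a Gaussian point-spread function (default FWHM 7 mm, a typical
  whole-body PET resolution) and spills into adjacent lung;
* *tumor* — an intrapulmonary soft-tissue sphere with high uptake and the
  same blurred spill;
* *diaphragm cold-spot* — a basal band of lung where uptake is scaled down,
  emulating respiratory attenuation mismatch.

The truth bundle carries the exact lung mask, airway mask, per-artifact
exclusion masks, and the biomarker panel of the clean unblurred lung draws.
Deliberately **not** modelled: scatter/randoms, reconstruction physics,
respiratory motion, lobar anatomy, and spatial texture in the lung uptake
(values are i.i.d., so the point-spread blur is applied to the artifact
blobs, where it creates the spill-over that matters, not to the lung field
itself).  Passing phantom tests therefore demonstrates that the *pipeline
logic* — thresholding, connectivity, exclusion accounting, percentile
arithmetic — is correct, not that segmentation would meet the same Dice on
clinical CT.

**Cohort simulator** (`simulate_cohort`).  Covariates are drawn
independently (their joint clinical correlation structure is unreported, so
independence is the default): age ~ N(64, 8) truncated to [35, 90], V30 ~
N(23.8, 8) truncated to [0, 60], and SUV95 lognormal with meanlog 0.08614
and sdlog 0.22331 — solved so its terciles fall at 0.99 and 1.2.  The
symptomatic indicator is Bernoulli with logit
`−16.146 + 0.40·(SUV95/0.1) + 0.79·(age/5) + 0.09·V30`; the slopes are the
published multiple-regression estimates on their stated scales (SUV95 per
0.1 units — each 0.1 increase multiplies the odds by 1.5 — age per 5 years
by package default since the published age scaling is ambiguous, V30 per
percentage point), and the intercept is calibrated once so the marginal
symptomatic rate is 59%.  Time to symptoms follows a proportional-hazards
exponential model with log-hazard
`0.18·(SUV95/0.1) + 0.34·(age/5) + 0.05·V30` and baseline hazard
2.5 × 10⁻⁶/day, calibrated once so the Kaplan–Meier median time in the
upper two SUV95 terciles is ≈ 101 days; administrative censoring is at 183
days (the 6-month scoring window).

A single binary outcome cannot be exactly marginal-logistic *and* have its
event time exactly exponential-PH: the implied event probability of the
survival mechanism is complementary-log-log in the covariates, not
logistic.  The default `endpoint = "both"` therefore takes the logistic
indicator as primary and draws symptomatic patients' times from the
Cox-exponential model truncated to the scoring window (every event implies
grade ≥ 2, and asymptomatic patients are censored at day 183);
`endpoint = "survival"` instead defines the event as "time ≤ 183 days",
the faithful generating mechanism for Cox parameter-recovery experiments.
Remaining columns (grades within the symptomatic/asymptomatic split, the
rest of the SUV/HU/dose panels, pulmonary function, demographics) are
dressing drawn to respect the record invariants (panel orderings,
V5 ≥ V10 ≥ V20 ≥ V30) and carry no signal.

**Reader simulator** (`simulate_reader_readings`).  Readings are
`subject value × (1 + ε)`, ε ~ N(0, inter-reader SD); with a 3% SD the
Bland–Altman limits of agreement are ±1.96 × 3 ≈ ±5.9% in expectation.

## Numerical and design choices

* **Percentile estimator**: type 7 (rank `1 + p(n−1)` interpolation), the
  common scientific-software default; configurable.
* **Otsu with fallback**: the histogram method is unspecified beyond
  "histogram segmentation"; Otsu is the canonical bimodal choice, and a
  fixed −400 HU fallback (plus a manual override) guards against degenerate
  histograms.
* **Connectivity**: 26 for lung components (tolerant to thin diagonal
  bridges), 6 for airway growth (prevents leaking through the thin airway
  wall).
* **Strict Vx inequality**: "irradiated to above x Gy" is read as `> x`;
  ties sit exactly on the threshold only on synthetic grids, and the tests
  pin the behaviour.
* **2 × 2 chi-squared with Yates correction**: reproduces the reference
  study's printed gender p-value (0.65; the uncorrected statistic gives
  ≈ 0.50).
* **Cox ties**: Efron, the modern default.
* **CI multiplier**: fixed 1.96 everywhere; printed intervals that disagree
  with `exp(coef ± 1.96·SE)` of the *rounded* published inputs are treated
  as pre-rounding artifacts, not chased.
* **Agreement limits**: ±1.96·√(within-subject mean square) from the
  one-way ANOVA with subject as the factor (residual df = N − n_subjects);
  this is the definition consistent with the closed-form 3% → ±5.9%
  behaviour.
* **Backward-AIC selection**: classic stepwise drop of the term whose
  removal lowers AIC most.  Note that AIC is *not* selection-consistent: a
  pure-noise term survives with probability P(χ²₁ > 2) ≈ 0.157, so with
  five inactive candidates the probability of recovering exactly the active
  set plateaus near 0.42 at any sample size, although the active terms
  themselves are essentially always retained.  The test suite documents
  both facts.
* **Degenerate inputs**: single-voxel ROIs report SD 0 with a warning;
  constant ROC scores report AUC 0.5 with an undefined interval flag;
  single-class partitions return a single leaf; a lung-free CT or an
  all-excluded ROI is an error, never an empty result.
* **Determinism**: phantoms, cohorts and readings restore the caller's RNG
  state and are bit-identical for a fixed spec + seed; segmentation is
  fully deterministic.

## Problem sizes used by the test suite

Module tests run on 48³ phantoms (≈ 17 000 lung voxels) and cohorts of
100–1000; the end-to-end recovery checks use the default 96 × 96 × 80
phantom (≈ 10⁵ lung voxels, where the empirical 95th percentile of the
clean draws sits within ±0.02 of the designed value), 10⁴-patient cohorts
for slope recovery, 200 replicates of n = 500 for confidence-interval
coverage, and 100 replicates of n = 2000 for the selection study.  These
sizes were chosen to make Monte-Carlo error small relative to each
assertion's tolerance.

## Known limitations

* The phantom exercises segmentation logic, not anatomical realism; Dice
  scores on it are upper bounds for clinical performance.
* The cohort simulator draws covariates independently and uses an
  exponential baseline hazard — the simplest PH-compatible choice — so it
  reproduces published coefficient structure, not the original joint data.
  Data-dependent headline numbers of the reference analysis (AUC, Youden
  operating point, partition thresholds, tercile hazard ratios, the ±6.1%
  agreement limits) are reproduced only *structurally*, not numerically.
* Out of scope by design: DICOM/DICOM-RT import, PET reconstruction and
  attenuation-correction physics, 4D-CT motion correction, lobe
  segmentation, treatment-planning interoperability, and SUV variants
  normalised by lean body mass or body surface area.
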