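# petrp

Pre-treatment FDG-PET lung biomarkers and radiation pneumonitis (RP) risk
modelling.

Thoracic radiotherapy patients with diffusely elevated baseline lung FDG
uptake — quantified by the upper percentiles of the standard-uptake-value
(SUV) distribution over the lungs, especially the 95th percentile
**SUV95** — are at increased risk of symptomatic (CTCAE grade ≥ 2)
radiation pneumonitis.  `petrp` is an R package for radiation-oncology and
imaging researchers that implements the full quantification-and-analysis
chain:

* **SUV conversion** — `SUV = activity (Bq/mL) × body weight (g) /
  (injected dose × 2^(−t/T½))`, with explicit ¹⁸F decay correction;
* **lung segmentation** — Otsu histogram thresholding of the CT, removal of
  exterior air by border connectivity, the two largest 26-connected
  components, central-airway removal by 6-connected region growing, and
  subtraction of artifact exclusion masks (cardiac/tumor PET spill-over,
  diaphragm cold-spots);
* **biomarkers** — mean, SD, max and the 80th/90th/95th percentiles of SUV
  and HU over the lung ROI (rank-interpolation percentiles);
* **dosimetry** — mean lung dose and V5/V10/V20/V30 (percent of lung
  receiving strictly more than x Gy/CGE), with RBE-1.1 proton conversion;
* **outcome statistics** — chi-squared / Mann–Whitney association tests,
  univariate logistic panels with Holm adjustment, backward-AIC multiple
  logistic regression (odds ratios `exp(β)`, 95% CIs
  `exp(β ± 1.96·SE)`, Nagelkerke R²), ROC with DeLong confidence
  intervals and the Youden cutpoint, depth-2 recursive partitioning,
  Kaplan–Meier SUV95 terciles, Cox proportional-hazards regression (Efron
  ties), and Bland–Altman inter-reader limits of agreement;
* **synthetic data** — ground-truthed thoracic phantoms and simulated
  100-patient cohorts so the entire pipeline runs and is tested without
  any patient data.

Volumes are read and written as NIfTI with JSON sidecars (RNifti), cohorts
as CSV; all generators are bit-reproducible under a fixed seed.

## Worked example

```r
library(petrp)

# a phantom with all three PET artifact classes
spec <- phantom_spec(include_cardiac_spillover = TRUE, include_tumor = TRUE,
                     include_diaphragm_coldspot = TRUE, seed = 7)
ph  <- generate_phantom(spec)
par <- segment_lung_parenchyma(ph$ct)
aw  <- extract_central_airway(ph$ct, par)
roi <- finalize_lung_roi(par, aw, list(
  exclusion_roi(ph$truth$artifact_masks$spill_over, "spill_over"),
  exclusion_roi(ph$truth$artifact_masks$cold_spot,  "cold_spot"),
  exclusion_roi(ph$truth$artifact_masks$tumor,      "tumor")))

dice(par, ph$truth$lung_plus_airway_mask)
#> [1] 0.9955552
summarize_roi(ph$pet, roi)
#> <uptake_summary SUV> n=103429  mean=0.8214 sd=0.2118 max=3.165  p80=0.9813 p90=1.096 p95=1.201
dose_metrics(ph$dose, roi)
#> <dose_metrics> MLD 20.2 Gy;  V5=65.3%  V10=56.0%  V20=42.9%  V30=30.9%
```

The segmentation overlaps the true lung mask with Dice 0.996, and the
measured SUV95 (1.201) recovers the phantom's designed 95th percentile
(1.200) once the spill-over and cold-spot regions are excluded — without
the exclusions it is biased upward (1.235).

```r
# a simulated cohort with the published coefficient structure, full study
co <- simulate_cohort(cohort_config(n_patients = 100, seed = 11))
run_study(co)
#> RP outcome study: 100 patients, 52 (52%) symptomatic (grade >= 2)
#> Univariate panel: 19 predictors; Holm over the 6 SUV predictors rejects 5
#> Multiple logistic (backward AIC):  suv_p95 + v30 + age + dlco_pct
#> ROC: AUC = 0.819 (DeLong 95% CI 0.737 - 0.900)
#> Youden point: threshold 0.4867, sensitivity 85%, specificity 69%
#> ...
```

`run_study()` returns an `rp_study` object whose components (`univariate`,
`holm`, `multiple_logistic`, `roc`, `partition`, `km`, `cox`) carry the
fitted tables; odds/hazard ratios are always `exp` of the coefficients with
`exp(β ± 1.96·SE)` intervals.  A thin command-line front end
(`inst/scripts/petrp`) exposes `phantom`, `simulate-cohort`, `extract`,
`analyze` and `demo` subcommands over the same functions.

See `vignettes/petrp-methods.Rmd` for the model, the generator
calibrations, and every numerical design choice.

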