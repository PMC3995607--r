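# Orchestration: per-case biomarker extraction (SUV conversion ->
# segmentation -> biomarkers -> dosimetry) and the cohort-level statistical
# study, both deterministic given their configuration.

#' Pipeline configuration
#'
#' @param alpha two-sided significance level (0 < alpha < 1).
#' @param percentile_type percentile estimator type (see [pctl()]).
#' @param dose_thresholds Vx thresholds in Gy/CGE.
#' @param hu_threshold optional manual segmentation threshold override.
#' @param paper_compat_terciles pin KM tercile boundaries at 0.99 / 1.2
#'   instead of the empirical terciles.
#' @param rbe proton RBE factor for CGE conversion.
#' @param assume_suv treat PET input as SUV even if metadata is present.
#' @param seed integer seed for any stochastic downstream step.
#' @return a `pipeline_config`; serialises losslessly through JSON.
#' @export
pipeline_config <- function(alpha = 0.05, percentile_type = 7,
                            dose_thresholds = c(5, 10, 20, 30),
                            hu_threshold = NULL,
                            paper_compat_terciles = FALSE,
                            rbe = 1.1, assume_suv = FALSE, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = alpha, percentile_type = percentile_type,
                 dose_thresholds = dose_thresholds,
                 hu_threshold = hu_threshold,
                 paper_compat_terciles = isTRUE(paper_compat_terciles),
                 rbe = rbe, assume_suv = isTRUE(assume_suv),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' Every output written by the pipeline carries this hash so results from
#' different configurations are detectable.
#' @param config a [pipeline_config()].
#' @return character md5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

load_vol <- function(x) if (is.character(x)) read_volume(x) else x

#' Run the per-case imaging pipeline
#'
#' CT (+ optional PET, dose, exclusion masks) in; one biomarker/dose CSV
#' row out.  Stages: SUV conversion (if the PET is an activity volume and
#' metadata is supplied) -> lung segmentation and airway removal ->
#' exclusion subtraction -> SUV and HU biomarker panels -> dose metrics.
#' Any stage error aborts the case with the stage named.
#'
#' @param case_id identifier written into the row.
#' @param ct `image_volume` (CT_HU) or NIfTI path.
#' @param pet optional PET volume/path (PET_SUV or PET_ACTIVITY).
#' @param dose optional dose volume/path.
#' @param meta optional [acquisition_meta()] (or path to its JSON sidecar)
#'   for activity-to-SUV conversion.
#' @param exclusions list of [exclusion_roi()] objects (the reproducible
#'   stand-in for manual artifact contours).
#' @param config a [pipeline_config()].
#' @return one-row `data.frame`; provenance (ordered stage log, config
#'   hash) in attribute `"provenance"`.
#' @export
run_case <- function(case_id, ct, pet = NULL, dose = NULL, meta = NULL,
                     exclusions = list(), config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("case ", case_id, " failed at stage [", name, "]: ",
           conditionMessage(e), call. = FALSE))
  }
  prov <- character()
  ct <- stage("load", load_vol(ct))
  if (is.character(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    meta <- acquisition_meta(m$injected_dose_Bq, m$injection_to_scan_min,
                             m$body_weight_g,
                             if (!is.null(m$half_life_min)) m$half_life_min
                             else 109.771)
  }
  parenchyma <- stage("segmentation",
                      segment_lung_parenchyma(ct, threshold = config$hu_threshold))
  airway <- stage("airway", extract_central_airway(ct, parenchyma))
  roi <- stage("roi", finalize_lung_roi(parenchyma, airway, exclusions))
  prov <- c(prov, roi$provenance)

  row <- data.frame(case_id = case_id, n_roi_voxels = roi$voxel_count,
                    stringsAsFactors = FALSE)
  hu <- stage("hu_biomarkers",
              summarize_roi(ct, roi, type = config$percentile_type))
  for (f in c("mean", "sd", "max", "p80", "p90", "p95"))
    row[[paste0("hu_", f)]] <- hu[[f]]

  if (!is.null(pet)) {
    pet <- stage("load", load_vol(pet))
    if (pet$modality == "PET_ACTIVITY" && !config$assume_suv) {
      if (is.null(meta))
        stage("suv_conversion",
              stop("PET is an activity volume but no acquisition metadata given"))
      pet <- stage("suv_conversion", activity_to_suv(pet, meta))
      prov <- c(prov, "suv: converted from activity (decay-corrected)")
    }
    if (!same_grid(pet, ct)) {
      pet <- stage("resample", resample_to_grid(pet, ct))
      prov <- c(prov, "pet: resampled to CT grid (trilinear)")
    }
    suv <- stage("suv_biomarkers",
                 summarize_roi(pet, roi, type = config$percentile_type))
    for (f in c("mean", "sd", "max", "p80", "p90", "p95"))
      row[[paste0("suv_", f)]] <- suv[[f]]
  } else {
    for (f in c("mean", "sd", "max", "p80", "p90", "p95"))
      row[[paste0("suv_", f)]] <- NA_real_
  }

  if (!is.null(dose)) {
    dose <- stage("load", load_vol(dose))
    if (!same_grid(dose, ct)) {
      dose <- stage("resample", resample_to_grid(dose, ct))
      prov <- c(prov, "dose: resampled to CT grid (trilinear)")
    }
    dm <- stage("dosimetry",
                dose_metrics(dose, roi, thresholds = config$dose_thresholds))
    row$mld <- dm$mld
    for (t in config$dose_thresholds)
      row[[paste0("v", t)]] <- dm[[paste0("v", t)]]
    row$dose_unit <- dm$unit
  } else {
    warning("case ", case_id, ": no dose volume; dose fields left empty")
    row$mld <- NA_real_
    for (t in config$dose_thresholds) row[[paste0("v", t)]] <- NA_real_
    row$dose_unit <- NA_character_
  }
  attr(row, "provenance") <- list(steps = prov, config_hash = config_hash(config))
  row
}

#' Run a batch of cases, continuing past per-case failures
#'
#' @param cases named list; each element is a list of arguments for
#'   [run_case()] (minus `config`).
#' @param config a [pipeline_config()].
#' @return list with `rows` (combined data frame of successful cases) and
#'   `errors` (named character vector of failure messages).
#' @export
run_cases <- function(cases, config = pipeline_config()) {
  rows <- list(); errors <- character()
  for (id in names(cases)) {
    res <- tryCatch(do.call(run_case, c(list(case_id = id), cases[[id]],
                                        list(config = config))),
                    error = function(e) e)
    if (inherits(res, "error")) errors[id] <- conditionMessage(res)
    else rows[[id]] <- res
  }
  list(rows = if (length(rows)) do.call(rbind, rows) else NULL,
       errors = errors)
}

.SUV_PREDICTORS <- c("suv_mean", "suv_sd", "suv_max",
                     "suv_p80", "suv_p90", "suv_p95")
.DEFAULT_UNIVARIATE <- c(.SUV_PREDICTORS,
                         "hu_mean", "hu_sd", "hu_max",
                         "hu_p80", "hu_p90", "hu_p95",
                         "mld", "v5", "v10", "v20", "v30",
                         "fev1_pct", "dlco_pct")
.DEFAULT_CANDIDATES <- c("suv_p95", "v30", "age", "mld",
                         "fev1_pct", "dlco_pct", "sex", "interval_days")

#' Run the cohort-level outcome study
#'
#' The full statistical battery on a patient-record table: association
#' tests for the categorical/continuous clinical covariates, the
#' univariate logistic panel, Holm adjustment over the six SUV predictors,
#' backward-AIC multiple logistic regression, ROC with DeLong CI and
#' Youden point on the multiple-model risk score, the depth-2 recursive
#' partition on SUV95 and V30, Kaplan-Meier SUV95 terciles, and a
#' backward-AIC Cox model.  Survival analyses are skipped with a notice if
#' the cohort has no events.
#'
#' @param cohort data frame of patient records (see [simulate_cohort()] for
#'   the column dictionary) or a CSV path.
#' @param config a [pipeline_config()].
#' @param univariate_predictors,candidates predictor sets for the
#'   univariate panel and the multiple-model selection.
#' @param output_dir optional directory; when given, result tables are
#'   written as CSV/JSON (with the config hash) and figures as PNG if a
#'   graphics device is available.
#' @return an object of class `rp_study`.
#' @export
run_study <- function(cohort, config = pipeline_config(),
                      univariate_predictors = .DEFAULT_UNIVARIATE,
                      candidates = .DEFAULT_CANDIDATES,
                      output_dir = NULL) {
  if (is.character(cohort)) cohort <- read.csv(cohort, stringsAsFactors = FALSE)
  y <- as.logical(cohort$symptomatic)
  if (length(unique(y)) < 2)
    stop("outcome column `symptomatic` is constant; the study is undefined")
  notices <- character()

  assoc_vars <- intersect(c("sex", "stage", "tumor_location", "histology",
                            "treatment_type", "chemo_status", "smoking",
                            "age", "interval_days"), names(cohort))
  association <- do.call(rbind, lapply(assoc_vars, function(v) {
    a <- tryCatch(association_tests(cohort, v), error = function(e) NULL)
    if (is.null(a)) return(NULL)
    data.frame(covariate = v, test = a$test, statistic = a$statistic,
               df = a$df, p_value = a$p_value, stringsAsFactors = FALSE)
  }))

  univariate_predictors <- intersect(univariate_predictors, names(cohort))
  univariate <- do.call(rbind, lapply(univariate_predictors, function(v) {
    f <- tryCatch(fit_logistic(v, cohort), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    tab <- f$table[f$table$term == v, ]
    data.frame(predictor = v, coef = tab$coef, se = tab$se, or = tab$or,
               or_lo = tab$or_lo, or_hi = tab$or_hi, p_value = tab$p,
               stringsAsFactors = FALSE)
  }))

  suv_rows <- univariate$predictor %in% .SUV_PREDICTORS
  holm <- cbind(predictor = univariate$predictor[suv_rows],
                holm_adjust(univariate$p_value[suv_rows],
                            alpha = config$alpha))

  multi <- backward_aic_select(cohort, candidates, family = "logistic")

  roc <- NULL; partition <- NULL
  if (!is.null(multi$fit)) {
    scores <- predict(multi$fit, newdata = cohort, type = "response")
    roc <- roc_delong_youden(scores, y)
  }
  partition <- recursive_partition(cohort)

  km <- NULL; cox <- NULL
  if (sum(cohort$event, na.rm = TRUE) == 0) {
    notices <- c(notices, "no events: Kaplan-Meier and Cox analyses skipped")
  } else {
    km <- km_fit(cohort, paper_compat = config$paper_compat_terciles)
    cox <- tryCatch(
      backward_aic_select(cohort, candidates, family = "cox"),
      error = function(e) {
        notices <<- c(notices, paste("Cox selection failed:",
                                     conditionMessage(e)))
        NULL
      })
  }

  out <- structure(list(
    n = nrow(cohort), n_symptomatic = sum(y),
    association = association, univariate = univariate, holm = holm,
    multiple_logistic = multi, roc = roc, partition = partition,
    km = km, cox = cox, notices = notices, config = config,
    config_hash = config_hash(config)), class = "rp_study")
  if (!is.null(output_dir)) write_study(out, output_dir)
  out
}

write_study <- function(study, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- study$config_hash; df }
  write.csv(stamp(study$univariate),
            file.path(output_dir, "univariate_logistic.csv"), row.names = FALSE)
  write.csv(stamp(study$holm),
            file.path(output_dir, "holm_suv.csv"), row.names = FALSE)
  if (!is.null(study$multiple_logistic$fit))
    write.csv(stamp(study$multiple_logistic$fit$table),
              file.path(output_dir, "multiple_logistic.csv"), row.names = FALSE)
  if (!is.null(study$cox) && !is.null(study$cox$fit))
    write.csv(stamp(study$cox$fit$table),
              file.path(output_dir, "cox.csv"), row.names = FALSE)
  manifest <- list(config = unclass(study$config),
                   config_hash = study$config_hash,
                   n = study$n, n_symptomatic = study$n_symptomatic,
                   notices = study$notices)
  if (!is.null(study$roc))
    manifest$roc <- study$roc[c("auc", "auc_ci_95", "youden_threshold",
                                "youden_sensitivity", "youden_specificity")]
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  if (capabilities("png")) {
    if (!is.null(study$roc) && isTRUE(study$roc$ci_defined)) {
      grDevices::png(file.path(output_dir, "roc.png"), 600, 600)
      plot(study$roc); grDevices::dev.off()
    }
    if (!is.null(study$km)) {
      grDevices::png(file.path(output_dir, "km_terciles.png"), 600, 600)
      plot(study$km); grDevices::dev.off()
    }
  }
  invisible(output_dir)
}

#' @export
print.rp_study <- function(x, ...) {
  cat(sprintf("RP outcome study: %d patients, %d (%d%%) symptomatic (grade >= 2)\n",
              x$n, x$n_symptomatic, round(100 * x$n_symptomatic / x$n)))
  cat(sprintf("Univariate panel: %d predictors; Holm over the %d SUV predictors rejects %d\n",
              nrow(x$univariate), nrow(x$holm), sum(x$holm$reject)))
  cat("Multiple logistic (backward AIC): ",
      paste(x$multiple_logistic$selected, collapse = " + "), "\n")
  if (!is.null(x$roc)) print(x$roc)
  if (!is.null(x$partition)) print(x$partition)
  if (!is.null(x$km)) print(x$km)
  if (!is.null(x$cox) && !is.null(x$cox$fit)) print(x$cox$fit)
  for (n in x$notices) cat("NOTE:", n, "\n")
  invisible(x)
}
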