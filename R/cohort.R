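# Simulated patient cohorts with the statistical structure the outcome
# analysis assumes: covariates drawn independently, a logistic model for the
# symptomatic (grade >= 2) pneumonitis indicator and a proportional-hazards
# exponential model for time to symptoms, administratively censored at the
# end of the 6-month scoring window.

#' Configure a simulated cohort
#'
#' Default coefficients are the published multiple-regression estimates the
#' pipeline is designed around: logistic slopes 0.40 per 0.1 SUV95, 0.79 per
#' 5 years of age, 0.09 per V30 percentage point; Cox log-hazards 0.18 per
#' 0.1 SUV95, 0.34 per 5 years, 0.05 per V30 point.  The intercept
#' (-16.146) is calibrated so the marginal symptomatic rate is 59% under the
#' default covariate distributions, and the baseline hazard (2.5e-6 / day)
#' so the Kaplan-Meier median time to symptoms in the upper two SUV95
#' terciles is about 101 days.  The SUV95 marginal is lognormal with
#' terciles at 0.99 and 1.2.
#'
#' @param n_patients number of patients (>= 10).
#' @param logistic_coefficients named vector `intercept`, `suv95`, `age`,
#'   `v30`; slopes on the scales given by `suv95_scale` / `age_scale`
#'   (V30 is per percentage point).
#' @param cox_coefficients named vector `suv95`, `age`, `v30` (same scales).
#' @param suv95_scale,age_scale units of the SUV95 and age slopes
#'   (default: per 0.1 SUV and per 5 years).
#' @param covariate_distributions list with elements `age` (`mean`, `sd`,
#'   `lo`, `hi`; truncated normal), `v30` (same), `suv95` (`meanlog`,
#'   `sdlog`; lognormal).
#' @param baseline_hazard exponential baseline hazard, events/day (> 0).
#' @param admin_censor_days administrative censoring cap, days (> 0).
#' @param endpoint `"both"` (default): symptomatic indicator from the
#'   logistic model, symptom times from the Cox-exponential model truncated
#'   to the scoring window so that every event implies grade >= 2;
#'   `"survival"`: the event is purely "symptom time <= cap", the faithful
#'   generating mechanism for Cox parameter-recovery studies.
#' @param seed integer RNG seed.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          logistic_coefficients = c(intercept = -16.146,
                                                    suv95 = 0.40,
                                                    age = 0.79,
                                                    v30 = 0.09),
                          cox_coefficients = c(suv95 = 0.18,
                                               age = 0.34,
                                               v30 = 0.05),
                          suv95_scale = 0.1, age_scale = 5,
                          covariate_distributions = list(
                            age   = c(mean = 64,   sd = 8, lo = 35, hi = 90),
                            v30   = c(mean = 23.8, sd = 8, lo = 0,  hi = 60),
                            suv95 = c(meanlog = 0.08613561, sdlog = 0.22331046)),
                          baseline_hazard = 2.5e-6,
                          admin_censor_days = 183,
                          endpoint = c("both", "survival"),
                          seed = 1L) {
  if (n_patients < 10) stop("n_patients must be >= 10")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (admin_censor_days <= 0) stop("admin_censor_days must be > 0")
  req <- function(x, nm) {
    if (!all(nm %in% names(x)))
      stop("missing coefficient(s): ", paste(setdiff(nm, names(x)), collapse = ", "))
    x[nm]
  }
  structure(list(
    n_patients = as.integer(n_patients),
    logistic_coefficients = req(logistic_coefficients,
                                c("intercept", "suv95", "age", "v30")),
    cox_coefficients = req(cox_coefficients, c("suv95", "age", "v30")),
    suv95_scale = suv95_scale, age_scale = age_scale,
    covariate_distributions = covariate_distributions,
    baseline_hazard = baseline_hazard,
    admin_censor_days = admin_censor_days,
    endpoint = match.arg(endpoint),
    seed = as.integer(seed)), class = "cohort_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

# CTCAE grade frequencies used to dress the binary outcome up as grades
.GRADE_PROBS_SYMPT <- c(`2` = 27, `3` = 23, `4` = 1, `5` = 8) / 59
.GRADE_PROBS_ASYMPT <- c(`0` = 10, `1` = 31) / 41

#' Simulate a patient cohort
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` (class `rp_cohort`) with one row per patient:
#'   demographics and treatment categories, the SUV and HU biomarker panels,
#'   dose metrics (`mld`, `v5` >= `v10` >= `v20` >= `v30`), pulmonary
#'   function, `rp_grade` (0-5), `symptomatic` (grade >= 2), `time_days` and
#'   `event`.  The generating config is attached as attribute `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_patients
  cd <- config$covariate_distributions

  age <- rtruncnorm1(n, cd$age["mean"], cd$age["sd"], cd$age["lo"], cd$age["hi"])
  v30 <- rtruncnorm1(n, cd$v30["mean"], cd$v30["sd"], cd$v30["lo"], cd$v30["hi"])
  suv95 <- rlnorm(n, cd$suv95["meanlog"], cd$suv95["sdlog"])

  lb <- config$logistic_coefficients
  lp_logit <- lb["intercept"] + lb["suv95"] * suv95 / config$suv95_scale +
    lb["age"] * age / config$age_scale + lb["v30"] * v30
  cb <- config$cox_coefficients
  lp_cox <- cb["suv95"] * suv95 / config$suv95_scale +
    cb["age"] * age / config$age_scale + cb["v30"] * v30
  if (any(!is.finite(lp_logit)) || any(!is.finite(lp_cox)))
    stop("non-finite linear predictor; check coefficients and covariate scales")

  cap <- config$admin_censor_days
  rate <- config$baseline_hazard * exp(lp_cox)
  if (config$endpoint == "survival") {
    t_raw <- -log(runif(n)) / rate
    event <- t_raw <= cap
    time_days <- pmin(t_raw, cap)
    symptomatic <- event
  } else {
    symptomatic <- rbinom(n, 1, plogis(lp_logit)) == 1
    # time to symptoms, truncated to the scoring window for symptomatic
    # patients (symptoms are by definition observed within the window)
    u <- runif(n)
    t_trunc <- -log(1 - u * (1 - exp(-rate * cap))) / rate
    time_days <- ifelse(symptomatic, t_trunc, cap)
    event <- symptomatic
  }
  time_days <- pmax(time_days, 1e-3)

  rp_grade <- integer(n)
  ns <- sum(symptomatic)
  rp_grade[symptomatic] <- sample(as.integer(names(.GRADE_PROBS_SYMPT)), ns,
                                  replace = TRUE, prob = .GRADE_PROBS_SYMPT)
  rp_grade[!symptomatic] <- sample(as.integer(names(.GRADE_PROBS_ASYMPT)),
                                   n - ns, replace = TRUE,
                                   prob = .GRADE_PROBS_ASYMPT)

  # remaining biomarker panel, dressed consistently around suv95
  suv_p90 <- suv95 * (1 - abs(rnorm(n, 0.04, 0.01)))
  suv_p80 <- suv_p90 * (1 - abs(rnorm(n, 0.06, 0.015)))
  suv_max <- suv95 * (1 + abs(rnorm(n, 0.8, 0.2)))
  suv_mean <- suv_p80 * (1 - abs(rnorm(n, 0.25, 0.04)))
  suv_sd <- suv95 * abs(rnorm(n, 0.20, 0.03))
  hu_mean <- rtruncnorm1(n, -780, 35, -950, -600)
  hu_sd <- abs(rnorm(n, 120, 20))
  hu_p80 <- hu_mean + 0.8 * hu_sd; hu_p90 <- hu_p80 + 0.45 * hu_sd
  hu_p95 <- hu_p90 + 0.35 * hu_sd; hu_max <- hu_p95 + abs(rnorm(n, 250, 60))
  mld <- rtruncnorm1(n, 17.9, 5.5, 1, 35)
  v20 <- pmin(v30 + abs(rnorm(n, 5, 2)), 100)
  v10 <- pmin(v20 + abs(rnorm(n, 7, 3)), 100)
  v5  <- pmin(v10 + abs(rnorm(n, 8, 3)), 100)
  fev1_pct <- rtruncnorm1(n, 72, 18, 25, 130)
  dlco_pct <- rtruncnorm1(n, 65, 20, 20, 130)

  out <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = as.numeric(age),
    sex = sample(c("M", "F"), n, TRUE, c(0.6, 0.4)),
    stage = sample(c("I", "II", "III", "IV"), n, TRUE, c(.06, .05, .78, .11)),
    tumor_location = sample(c("LLL", "LUL", "RLL", "RML", "RUL"), n, TRUE,
                            c(.15, .25, .09, .06, .45)),
    histology = sample(c("adeno", "squamous", "nsclc_nos", "neuroendocrine"),
                       n, TRUE, c(.57, .24, .18, .01)),
    treatment_type = sample(c("IMRT", "3DCRT", "proton"), n, TRUE,
                            c(.64, .23, .13)),
    chemo_status = sample(c("concurrent", "rt_alone"), n, TRUE, c(.86, .14)),
    smoking = sample(c("current", "former", "never"), n, TRUE, c(.28, .66, .06)),
    interval_days = round(pmin(pmax(rlnorm(n, log(18), 0.6), 3), 90)),
    suv_mean = suv_mean, suv_sd = suv_sd, suv_max = suv_max,
    suv_p80 = suv_p80, suv_p90 = suv_p90, suv_p95 = as.numeric(suv95),
    hu_mean = hu_mean, hu_sd = hu_sd, hu_max = hu_max,
    hu_p80 = hu_p80, hu_p90 = hu_p90, hu_p95 = hu_p95,
    mld = mld, v5 = v5, v10 = v10, v20 = v20, v30 = as.numeric(v30),
    fev1_pct = fev1_pct, dlco_pct = dlco_pct,
    rp_grade = rp_grade,
    symptomatic = as.logical(symptomatic),
    time_days = as.numeric(time_days),
    event = as.logical(event),
    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("rp_cohort", "data.frame")
  out
}

#' Specify an inter-reader reading simulation
#'
#' @param n_subjects,n_readers design (readers >= 2); the default 10 x 3
#'   mirrors a typical agreement substudy.
#' @param between_subject_sd_pct,inter_reader_sd_pct percent-scale SDs of
#'   the between-subject spread and of the multiplicative reader error.
#' @param subject_level central SUV95 level of the subjects.
#' @param seed integer RNG seed.
#' @return a `reader_sim_spec`.
#' @export
reader_sim_spec <- function(n_subjects = 10, n_readers = 3,
                            between_subject_sd_pct = 20,
                            inter_reader_sd_pct = 3,
                            subject_level = 1.1, seed = 1L) {
  if (n_readers < 2) stop("n_readers must be >= 2")
  if (between_subject_sd_pct < 0 || inter_reader_sd_pct < 0)
    stop("percent SDs must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_readers = as.integer(n_readers),
                 between_subject_sd_pct = between_subject_sd_pct,
                 inter_reader_sd_pct = inter_reader_sd_pct,
                 subject_level = subject_level, seed = as.integer(seed)),
            class = "reader_sim_spec")
}

#' Simulate repeated SUV95 readings by independent readers
#'
#' Each reading is `subject_value * (1 + e)` with `e ~ N(0,
#' inter_reader_sd_pct / 100)`; subject values spread multiplicatively
#' around `subject_level`.
#'
#' @param spec a [reader_sim_spec()].
#' @return numeric matrix, subjects x readers, with the true subject values
#'   as attribute `subject_values`.
#' @export
simulate_reader_readings <- function(spec = reader_sim_spec()) {
  stopifnot(inherits(spec, "reader_sim_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  sv <- spec$subject_level *
    exp(rnorm(spec$n_subjects, 0, spec$between_subject_sd_pct / 100))
  eps <- matrix(rnorm(spec$n_subjects * spec$n_readers, 0,
                      spec$inter_reader_sd_pct / 100),
                spec$n_subjects, spec$n_readers)
  out <- sv * (1 + eps)
  dimnames(out) <- list(subject = sprintf("S%02d", seq_len(spec$n_subjects)),
                        reader = sprintf("R%d", seq_len(spec$n_readers)))
  attr(out, "subject_values") <- sv
  out
}
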