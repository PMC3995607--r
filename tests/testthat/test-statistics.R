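test_that("association tests dispatch on covariate type", {
  # identical continuous groups: Mann-Whitney p = 1
  d <- data.frame(x = rep(c(1, 2, 3, 4, 5), 4),
                  symptomatic = rep(c(TRUE, FALSE), each = 10))
  a <- association_tests(d, "x")
  expect_identical(a$test, "mann-whitney")
  expect_gt(a$p_value, 0.99)

  # 2 x 2 with Yates correction: gender-by-outcome anchor table
  d2 <- data.frame(
    sex = rep(c("M", "F"), times = c(60, 40)),
    symptomatic = c(rep(TRUE, 35), rep(FALSE, 25), rep(TRUE, 26), rep(FALSE, 14)))
  a2 <- association_tests(d2, "sex")
  expect_identical(a2$test, "chi-squared")
  expect_equal(a2$statistic, 0.212, tolerance = 1e-2)
  expect_equal(a2$df, 1)
  expect_equal(a2$p_value, 0.645, tolerance = 1e-3)

  # perfect association
  d3 <- data.frame(g = rep(c("a", "b"), each = 50),
                   symptomatic = rep(c(TRUE, FALSE), each = 50))
  expect_lt(association_tests(d3, "g")$p_value, 1e-10)

  # empty expected cell
  d4 <- d3
  d4$g <- factor(d4$g, levels = c("a", "b", "c"))
  expect_error(association_tests(d4, "g"), "merge")
})

test_that("logistic fits expose ORs and CIs as exp of the coefficients", {
  co <- simulate_cohort(cohort_config(n_patients = 400, seed = 21))
  fit <- fit_logistic(c("suv_p95", "age", "v30"), co)
  tab <- fit$table
  expect_equal(tab$or, exp(tab$coef), tolerance = 1e-12)
  expect_equal(tab$or_lo, exp(tab$coef - 1.96 * tab$se), tolerance = 1e-12)
  expect_equal(tab$or_hi, exp(tab$coef + 1.96 * tab$se), tolerance = 1e-12)
  expect_gte(fit$nagelkerke_r2, 0)
  expect_lte(fit$nagelkerke_r2, 1)
  expect_equal(as.numeric(logLik(fit$fit)), fit$loglik)
})

test_that("degenerate logistic problems fail loudly", {
  d <- data.frame(x = 1:40, symptomatic = rep(c(FALSE, TRUE), each = 20))
  expect_error(fit_logistic("x", d), "separation|converge")
  d2 <- data.frame(x = rnorm(40), symptomatic = rep(TRUE, 40))
  expect_error(fit_logistic("x", d2), "constant")
  expect_error(fit_logistic("x", d[1:8, ]), "10")
})

test_that("Holm step-down rejects the documented sets", {
  # six univariate SUV p-values; all but the first survive at alpha 0.05
  p <- c(0.10, 0.02, 0.0057, 0.013, 0.0061, 0.0049)
  h <- holm_adjust(p, alpha = 0.05)
  expect_identical(h$reject, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(sum(h$reject), 5L)

  expect_identical(holm_adjust(rep(1, 6))$reject, rep(FALSE, 6))
  expect_identical(holm_adjust(0.04)$reject, TRUE)

  set.seed(5)
  praw <- runif(20)
  h2 <- holm_adjust(praw)
  expect_true(all(h2$p_adjusted >= praw))
  ord <- order(praw)
  expect_true(all(diff(h2$p_adjusted[ord]) >= -1e-15))
})

test_that("Nagelkerke R2 matches the plug-in formula and its bounds", {
  expect_equal(nagelkerke_r2(-5, -5, 20), 0)
  # hand case: n = 4, LL0 = -2.7726 (= 4 log 2), LL1 = -1.3863
  r2 <- (1 - exp((2 / 4) * (-2.7726 + 1.3863))) / (1 - exp((2 / 4) * -2.7726))
  expect_equal(nagelkerke_r2(-1.3863, -2.7726, 4), r2, tolerance = 1e-12)
  expect_equal(r2, 0.6667, tolerance = 1e-4)
  # perfect prediction saturates at 1
  expect_equal(nagelkerke_r2(-1e-10, -50, 100), 1, tolerance = 1e-3)
  expect_error(nagelkerke_r2(-10, -5, 20), "null")
})

test_that("AUC matches the pairwise-concordance oracle", {
  r1 <- roc_delong_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r1$auc, 1.0)
  expect_equal(r1$youden_sensitivity + r1$youden_specificity - 1, 1.0)
  r2 <- roc_delong_youden(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$auc, 0.75)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    sc <- sample(rnorm(n %/% 2 + 5), n, replace = TRUE)  # force some ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2 || length(unique(sc)) < 2) next
    expect_equal(roc_delong_youden(sc, y)$auc, oracle_auc(sc, y),
                 tolerance = 1e-12)
  }
})

test_that("the Youden point maximises J with ties broken to specificity", {
  set.seed(32)
  sc <- round(runif(60), 1)
  y <- rbinom(60, 1, plogis(3 * sc - 1.5))
  r <- roc_delong_youden(sc, y)
  j <- r$sensitivity + r$specificity - 1
  expect_equal(r$youden_sensitivity + r$youden_specificity - 1, max(j))
  best <- which(j == max(j))
  expect_equal(r$youden_specificity, max(r$specificity[best]))
})

test_that("constant scores degrade gracefully", {
  expect_warning(r <- roc_delong_youden(rep(1, 20), rep(c(0, 1), 10)),
                 "constant")
  expect_equal(r$auc, 0.5)
  expect_false(r$ci_defined)
})

test_that("the depth-2 partition recovers a noise-free OR rule", {
  set.seed(3)
  n <- 500
  d <- data.frame(suv_p95 = runif(n, 0.5, 1.6), v30 = runif(n, 5, 45))
  d$symptomatic <- d$suv_p95 > 1.0 | d$v30 > 25
  p <- recursive_partition(d)
  expect_identical(nrow(p$splits), 2L)
  expect_setequal(p$splits$variable, c("suv_p95", "v30"))
  expect_true(all(p$splits$symptomatic_side == "high"))
  thr_suv <- p$splits$threshold[p$splits$variable == "suv_p95"]
  thr_v30 <- p$splits$threshold[p$splits$variable == "v30"]
  gap_suv <- max(diff(sort(unique(d$suv_p95))))
  gap_v30 <- max(diff(sort(unique(d$v30))))
  expect_lt(abs(thr_suv - 1.0), gap_suv + 1e-9)
  expect_lt(abs(thr_v30 - 25), gap_v30 + 1e-9)
  expect_equal(p$sensitivity, 1.0)
  expect_equal(p$specificity, 1.0)
})

test_that("single-class data yields a single leaf, not an error", {
  d <- data.frame(suv_p95 = runif(30), v30 = runif(30, 5, 45),
                  symptomatic = rep(TRUE, 30))
  p <- recursive_partition(d)
  expect_identical(nrow(p$splits), 0L)
  expect_equal(p$sensitivity, 1)
})

test_that("partition thresholds lie strictly between observed values", {
  co <- simulate_cohort(cohort_config(n_patients = 200, seed = 41))
  p <- recursive_partition(co)
  for (i in seq_len(nrow(p$splits))) {
    v <- co[[p$splits$variable[i]]]
    expect_false(any(v == p$splits$threshold[i]))
    expect_gt(p$splits$threshold[i], min(v))
    expect_lt(p$splits$threshold[i], max(v))
  }
})

test_that("Kaplan-Meier matches the hand product-limit estimator", {
  d <- data.frame(time_days = c(1, 2, 3), event = TRUE, suv_p95 = 1)
  km <- km_fit(d, boundaries = c(0, 100))  # everyone in one stratum
  sf <- km$survfit
  expect_equal(sf$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(km$medians[!is.na(km$medians)]), 2)

  # no events: flat curve, absent median
  d0 <- data.frame(time_days = c(5, 8, 13), event = FALSE, suv_p95 = 1)
  km0 <- km_fit(d0, boundaries = c(0, 100))
  expect_true(all(km0$survfit$surv == 1))
  expect_true(all(is.na(km0$medians)))
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(51)
  t <- sample(1:400, 80, replace = TRUE)
  d <- data.frame(time_days = t, event = TRUE, suv_p95 = rnorm(80, 1, 0.1))
  km <- km_fit(d, boundaries = c(0, 100))  # single occupied stratum
  o <- oracle_km(d$time_days, d$event)
  sf <- km$survfit
  ev_times <- sf$time[sf$n.event > 0]
  expect_equal(ev_times, o$time)
  expect_equal(sf$surv[sf$n.event > 0], o$surv, tolerance = 1e-12)
})

test_that("tercile boundaries are empirical unless pinned", {
  co <- simulate_cohort(cohort_config(n_patients = 300, seed = 61))
  km <- km_fit(co)
  expect_equal(km$boundaries,
               unname(quantile(co$suv_p95, c(1, 2) / 3, type = 7)))
  kmp <- km_fit(co, paper_compat = TRUE)
  expect_equal(kmp$boundaries, c(0.99, 1.2))
  expect_identical(nrow(kmp$tercile_hr), 2L)
  expect_equal(kmp$tercile_hr$hr, exp(kmp$tercile_hr$coef), tolerance = 1e-12)
})

test_that("Cox fits expose HRs as exp of coefficients and detect no-effect terms", {
  co <- simulate_cohort(cohort_config(n_patients = 600, endpoint = "survival",
                                      seed = 71))
  co$noise <- rnorm(nrow(co))
  fit <- cox_fit(c("suv_p95", "noise"), co)
  tab <- fit$table
  expect_equal(tab$hr, exp(tab$coef), tolerance = 1e-12)
  expect_equal(tab$hr_lo, exp(tab$coef - 1.96 * tab$se), tolerance = 1e-12)
  noise_row <- tab[tab$term == "noise", ]
  expect_lt(abs(noise_row$coef), 2 * noise_row$se)
  expect_error(cox_fit("suv_p95", co[1:12, ]), "10 events")
})

test_that("backward AIC keeps a strong single candidate and is deterministic", {
  co <- simulate_cohort(cohort_config(n_patients = 1000, seed = 81))
  s1 <- backward_aic_select(co, "suv_p95")
  expect_identical(s1$selected, "suv_p95")
  s2 <- backward_aic_select(co, c("suv_p95", "v30", "age", "mld"))
  s3 <- backward_aic_select(co, c("suv_p95", "v30", "age", "mld"))
  expect_identical(s2$selected, s3$selected)
  expect_lte(s2$aic_selected, s2$aic_full + 1e-9)
  expect_error(backward_aic_select(co, character()), "empty")
  # cox family uses the partial-likelihood AIC
  sc <- backward_aic_select(co, c("suv_p95", "age"), family = "cox")
  expect_true(inherits(sc$fit, "rp_cox") || is.null(sc$fit))
})

test_that("pure-noise candidates are mostly eliminated", {
  set.seed(91)
  kept <- integer(0)
  for (i in 1:15) {
    n <- 2000
    d <- data.frame(symptomatic = rbinom(n, 1, 0.5) == 1,
                    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n))
    kept <- c(kept, length(backward_aic_select(d, c("n1", "n2", "n3", "n4"))$selected))
  }
  # AIC false-keep rate is ~0.157 per term => average well under 2 of 4
  expect_lt(mean(kept), 1.5)
})

test_that("Bland-Altman limits follow the one-way ANOVA within mean square", {
  same <- matrix(rep(c(1.0, 1.2, 0.9, 1.4), 3), ncol = 3)
  ba0 <- bland_altman_loa(same)
  expect_equal(ba0$loa_pct, 0)

  # 2 subjects x 2 readers, hand ANOVA: deviations +/-0.990099%,
  # SSw = 3.92118 on 2 df => sqrt(MSw) = 1.40021
  r <- rbind(c(100, 102), c(50, 51))
  ba <- bland_altman_loa(r)
  expect_equal(abs(as.vector(ba$deviations_pct)), rep(100 / 101, 4),
               tolerance = 1e-12)
  expect_equal(ba$loa_pct, 1.96 * 1.40021, tolerance = 1e-4)

  # closed form: 3% reader SD => LoA ~ +/-5.88%
  rr <- simulate_reader_readings(reader_sim_spec(n_subjects = 200, n_readers = 3,
                                                 inter_reader_sd_pct = 3, seed = 4))
  ba3 <- bland_altman_loa(rr)
  expect_lt(abs(ba3$loa_pct - 1.96 * 3), 0.7)
  expect_lt(abs(ba3$mean_deviation_pct), 0.05)
})

test_that("subjects with a single reading are excluded with a warning", {
  r <- rbind(c(100, 102), c(50, NA), c(80, 84))
  expect_warning(ba <- bland_altman_loa(r), "excluded")
  expect_identical(ba$n_subjects, 2L)
  expect_error(bland_altman_loa(rbind(c(1, 2))), "at least 2 subjects")
  expect_error(bland_altman_loa(rbind(c(1, -2), c(3, 4))), "> 0")
})
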