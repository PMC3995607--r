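test_that("constant lung SUV gives a degenerate truth panel", {
  sp <- small_spec(lung_suv_distribution = suv_distribution("constant", value = 0.7))
  ph <- generate_phantom(sp)
  s <- ph$truth$summary
  expect_equal(s$mean, 0.7)
  expect_equal(s$p80, 0.7)
  expect_equal(s$p90, 0.7)
  expect_equal(s$p95, 0.7)
  expect_equal(s$max, 0.7)
  expect_equal(s$sd, 0)
})

test_that("empirical truth percentiles converge to the designed distribution", {
  ph <- cached("default_clean", generate_phantom(phantom_spec(seed = 7)))
  expect_gte(ph$truth$summary$n_voxels, 1e5)
  designed <- designed_percentile(phantom_spec(seed = 7)$lung_suv_distribution, 95)
  expect_equal(designed, 1.2, tolerance = 1e-12)
  expect_lt(abs(ph$truth$summary$p95 - designed), 0.02)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  a <- generate_phantom(small_spec(include_cardiac_spillover = TRUE))
  b <- generate_phantom(small_spec(include_cardiac_spillover = TRUE))
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$dose$data, b$dose$data)
  expect_identical(a$truth$lung_mask$data, b$truth$lung_mask$data)
})

test_that("phantom spec validation catches degenerate grids", {
  expect_error(phantom_spec(grid_shape = c(8, 48, 48)), "at least")
  expect_error(phantom_spec(spacing_mm = c(0, 3, 3)), "positive")
  expect_error(phantom_spec(psf_fwhm_mm = -1), "psf_fwhm_mm")
})

test_that("null cohort slopes give a 50% symptomatic rate", {
  cfg <- cohort_config(n_patients = 1e4,
                       logistic_coefficients = c(intercept = 0, suv95 = 0,
                                                 age = 0, v30 = 0),
                       seed = 3)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$symptomatic) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("logistic refits on a large cohort recover the generating slopes", {
  co <- simulate_cohort(cohort_config(n_patients = 1e4, seed = 1))
  co$suv_s <- co$suv_p95 / 0.1
  co$age_s <- co$age / 5
  fit <- fit_logistic(c("suv_s", "age_s", "v30"), co)
  truth <- c(suv_s = 0.40, age_s = 0.79, v30 = 0.09)
  for (term in names(truth)) {
    row <- fit$table[fit$table$term == term, ]
    expect_lt(abs(row$coef - truth[[term]]), 2 * row$se)
  }
})

test_that("cox refits under the survival endpoint recover the log-hazards", {
  co <- simulate_cohort(cohort_config(n_patients = 4000,
                                      endpoint = "survival", seed = 2))
  co$suv_s <- co$suv_p95 / 0.1
  co$age_s <- co$age / 5
  fit <- cox_fit(c("suv_s", "age_s", "v30"), co)
  truth <- c(suv_s = 0.18, age_s = 0.34, v30 = 0.05)
  for (term in names(truth)) {
    row <- fit$table[fit$table$term == term, ]
    expect_lt(abs(row$coef - truth[[term]]), 2 * row$se)
  }
})

test_that("the default baseline hazard calibrates the upper-tercile median near 101 days", {
  co <- simulate_cohort(cohort_config(n_patients = 1e4, seed = 1))
  km <- km_fit(co, boundaries = c(0.99, 99))  # T2 = everyone with SUV95 >= 0.99
  med <- unname(km$medians[["g=T2"]])
  expect_gte(med, 90)
  expect_lte(med, 112)
})

test_that("cohort generation is deterministic and validates its config", {
  a <- simulate_cohort(cohort_config(seed = 9))
  b <- simulate_cohort(cohort_config(seed = 9))
  expect_identical(a, b)
  expect_error(cohort_config(n_patients = 5), ">= 10")
  expect_error(cohort_config(baseline_hazard = 0), "> 0")
  expect_error(
    simulate_cohort(cohort_config(
      logistic_coefficients = c(intercept = Inf, suv95 = 0, age = 0, v30 = 0))),
    "non-finite")
})

test_that("cohort records respect their structural invariants", {
  co <- simulate_cohort(cohort_config(n_patients = 500, seed = 4))
  expect_true(all(co$rp_grade %in% 0:5))
  expect_identical(co$symptomatic, co$rp_grade >= 2)
  expect_true(all(co$event <= co$symptomatic))
  expect_true(all(co$time_days > 0))
  expect_true(all(co$v5 >= co$v10 & co$v10 >= co$v20 & co$v20 >= co$v30))
  expect_true(all(co$suv_p80 <= co$suv_p90 & co$suv_p90 <= co$suv_p95 &
                    co$suv_p95 <= co$suv_max))
})

test_that("reader simulation follows the multiplicative error model", {
  r0 <- simulate_reader_readings(reader_sim_spec(inter_reader_sd_pct = 0, seed = 1))
  expect_equal(r0[, 1], r0[, 2])
  expect_equal(r0[, 1], r0[, 3])
  r <- simulate_reader_readings(reader_sim_spec(n_subjects = 10, n_readers = 3,
                                                seed = 2))
  expect_identical(dim(r), c(10L, 3L))
  expect_identical(r, simulate_reader_readings(reader_sim_spec(n_subjects = 10,
                                                               n_readers = 3,
                                                               seed = 2)))
  expect_error(reader_sim_spec(n_readers = 1), ">= 2")
  expect_error(reader_sim_spec(inter_reader_sd_pct = -1), ">= 0")
})
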