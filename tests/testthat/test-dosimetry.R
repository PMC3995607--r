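vol_of <- function(values, modality = "DOSE", unit = "Gy") {
  n <- length(values)
  d <- c(n, 1, 1)
  image_volume(array(values, d), c(3, 3, 3), modality, unit = unit)
}
mask_of <- function(n, which = seq_len(n)) {
  m <- array(FALSE, c(n, 1, 1)); m[which] <- TRUE
  binary_mask(m, spacing_mm = c(3, 3, 3))
}

test_that("Vx uses the strict 'above threshold' rule", {
  m <- dose_metrics(vol_of(rep(10, 8)), mask_of(8))
  expect_equal(m$mld, 10)
  expect_equal(m$v5, 100)
  expect_equal(m$v10, 0)  # exactly at threshold: not "above"
  expect_equal(m$v20, 0)
  expect_equal(m$v30, 0)

  m2 <- dose_metrics(vol_of(c(2, 10, 25, 35)), mask_of(4))
  expect_equal(m2$mld, 18)
  expect_equal(m2$v5, 75)
  expect_equal(m2$v10, 50)  # 10 Gy is not above 10 Gy
  expect_equal(m2$v20, 50)
  expect_equal(m2$v30, 25)

  z <- dose_metrics(vol_of(rep(0, 5)), mask_of(5))
  expect_equal(unlist(z[c("mld", "v5", "v10", "v20", "v30")]),
               c(mld = 0, v5 = 0, v10 = 0, v20 = 0, v30 = 0))
})

test_that("negative dose voxels are an error", {
  expect_error(dose_metrics(vol_of(c(1, -2, 3, -4)), mask_of(4)), "2 negative")
})

test_that("raising any voxel's dose never decreases a metric", {
  set.seed(11)
  for (i in 1:20) {
    d <- runif(50, 0, 40)
    m0 <- dose_metrics(vol_of(d), mask_of(50))
    j <- sample(50, 1)
    d[j] <- d[j] + runif(1, 0, 20)
    m1 <- dose_metrics(vol_of(d), mask_of(50))
    for (f in c("mld", "v5", "v10", "v20", "v30"))
      expect_gte(m1[[f]], m0[[f]])
  }
})

test_that("Vx equals 100 (1 - empirical CDF) and is non-increasing in x", {
  set.seed(12)
  d <- runif(200, 0, 50)
  thr <- c(5, 10, 20, 30, 40)
  m <- dose_metrics(vol_of(d), mask_of(200), thresholds = thr)
  vx <- unlist(m[paste0("v", thr)])
  expect_true(all(diff(vx) <= 0))
  ec <- stats::ecdf(d)
  for (t in thr)
    expect_equal(m[[paste0("v", t)]], 100 * (1 - ec(t)), tolerance = 1e-12)
})

test_that("CGE conversion applies the RBE once and shifts Vx thresholds", {
  v <- vol_of(rep(60, 4))
  cge <- to_cge(v, 1.1)
  expect_equal(unique(as.vector(cge$data)), 66)
  expect_identical(cge$unit, "CGE")
  expect_error(to_cge(cge), "twice")
  expect_equal(to_cge(v, 1.0)$data, v$data)

  u28 <- vol_of(rep(28, 4))
  expect_equal(dose_metrics(u28, mask_of(4))$v30, 0)
  expect_equal(dose_metrics(to_cge(u28), mask_of(4))$v30, 100)  # 30.8 CGE
})
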