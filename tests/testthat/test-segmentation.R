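test_that("histogram segmentation recovers the phantom lungs", {
  ph <- phantom_small_clean()
  par <- segmented_small_clean()$parenchyma
  expect_gte(dice(par, ph$truth$lung_plus_airway_mask), 0.95)
  expect_true(any(grepl("Otsu", par$provenance)))
})

test_that("a CT without lungs errors rather than returning an empty mask", {
  flat <- image_volume(array(40, c(32, 32, 32)), c(3, 3, 3), "CT_HU")
  expect_error(segment_lung_parenchyma(flat), "implausible")
  # plausible HU range but only one low-density component
  one <- array(40, c(32, 32, 32))
  one[10:20, 10:20, 10:20] <- -800
  expect_error(
    segment_lung_parenchyma(image_volume(one, c(3, 3, 3), "CT_HU")),
    "fewer than two")
})

test_that("the cardiac blob lives in PET, not CT: the CT mask is unchanged", {
  ph0 <- phantom_small_clean()
  ph1 <- generate_phantom(small_spec(include_cardiac_spillover = TRUE))
  d0 <- dice(segment_lung_parenchyma(ph0$ct), ph0$truth$lung_plus_airway_mask)
  d1 <- dice(segment_lung_parenchyma(ph1$ct), ph1$truth$lung_plus_airway_mask)
  expect_lt(abs(d0 - d1), 0.02)
})

test_that("airway extraction recovers the phantom airway and stays disjoint", {
  ph <- phantom_small_clean()
  seg <- segmented_small_clean()
  truth_aw <- ph$truth$airway_mask
  recall <- sum(seg$airway$data & truth_aw$data) / truth_aw$voxel_count
  expect_gte(recall, 0.90)
  expect_equal(sum(seg$airway$data & seg$roi$data), 0)
})

test_that("a phantom without an airway yields an empty mask with a warning", {
  ph <- generate_phantom(small_spec(include_airway = FALSE, seed = 3))
  par <- segment_lung_parenchyma(ph$ct)
  expect_warning(aw <- extract_central_airway(ph$ct, par), "no airway seed")
  expect_equal(aw$voxel_count, 0)
})

test_that("finalize is the identity without airway or exclusions", {
  seg <- segmented_small_clean()
  empty <- binary_mask(array(FALSE, dim(seg$parenchyma$data)),
                       reference = seg$parenchyma)
  roi <- finalize_lung_roi(seg$parenchyma, empty, list())
  expect_identical(roi$data, seg$parenchyma$data)
})

test_that("ROI voxel count is non-increasing through the pipeline steps", {
  ph <- phantom_small_artifacts()
  par <- segment_lung_parenchyma(ph$ct)
  aw <- extract_central_airway(ph$ct, par)
  roi1 <- finalize_lung_roi(par, aw)
  roi2 <- finalize_lung_roi(par, aw, list(
    exclusion_roi(ph$truth$artifact_masks$spill_over, "spill_over")))
  expect_lte(roi1$voxel_count, par$voxel_count)
  expect_lte(roi2$voxel_count, roi1$voxel_count)
  expect_true(all(roi2$data <= par$data))
  expect_true(any(grepl("minus spill_over", roi2$provenance)))
})

test_that("supplying artifact exclusions recovers the designed SUV95", {
  ph <- phantom_small_artifacts()
  par <- segment_lung_parenchyma(ph$ct)
  aw <- extract_central_airway(ph$ct, par)
  designed <- designed_percentile(ph$truth$spec$lung_suv_distribution, 95)
  roi_raw <- finalize_lung_roi(par, aw)
  ex <- list(exclusion_roi(ph$truth$artifact_masks$spill_over, "spill_over"),
             exclusion_roi(ph$truth$artifact_masks$cold_spot, "cold_spot"),
             exclusion_roi(ph$truth$artifact_masks$tumor, "tumor"))
  roi_ex <- finalize_lung_roi(par, aw, ex)
  p95_raw <- summarize_roi(ph$pet, roi_raw)$p95
  p95_ex <- summarize_roi(ph$pet, roi_ex)$p95
  expect_lt(abs(p95_ex - designed), 0.03)
  # spill-over inflates the uncorrected percentile
  expect_gt(p95_raw, p95_ex)
  expect_gt(abs(p95_raw - designed), abs(p95_ex - designed))
})

test_that("exclusions covering all of the parenchyma are an error", {
  seg <- segmented_small_clean()
  all_mask <- binary_mask(array(TRUE, dim(seg$parenchyma$data)),
                          reference = seg$parenchyma)
  expect_error(
    finalize_lung_roi(seg$parenchyma, NULL,
                      list(exclusion_roi(all_mask, "spill_over"))),
    "empty")
})

test_that("exclusion labels come from the fixed vocabulary", {
  seg <- segmented_small_clean()
  expect_error(exclusion_roi(seg$parenchyma, "blob"))
  expect_identical(exclusion_roi(seg$parenchyma, "cold_spot")$label, "cold_spot")
})
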