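# Thoracic software phantom: two ellipsoidal lungs in a soft-tissue thorax
# with an air-filled central airway, optional PET artifacts (cardiac
# spill-over, hot tumor, diaphragm cold-spot) and a smooth dose field.
# All anatomy scales with the physical grid extent so any grid of at least
# 16 voxels per axis contains the structures.

#' Describe a lung SUV distribution
#'
#' Lung voxel values are drawn i.i.d. from this marginal distribution.  For
#' `"lognormal"` either give `meanlog`/`sdlog` directly, or give the target
#' 95th percentile `p95` together with `sdlog` and `meanlog` is solved so
#' the designed distribution has exactly that percentile.
#'
#' @param name `"lognormal"` or `"constant"`.
#' @param p95 designed 95th percentile (lognormal only).
#' @param sdlog log-scale SD (lognormal only; default 0.25).
#' @param meanlog log-scale mean (alternative to `p95`).
#' @param value constant value (`"constant"` only).
#' @return a `suv_distribution` specification.
#' @export
suv_distribution <- function(name = c("lognormal", "constant"),
                             p95 = NULL, sdlog = 0.25, meanlog = NULL,
                             value = NULL) {
  name <- match.arg(name)
  if (name == "constant") {
    if (is.null(value) || value < 0) stop("constant distribution needs `value` >= 0")
    out <- list(name = "constant", value = value)
  } else {
    if (is.null(meanlog)) {
      if (is.null(p95)) stop("give `p95` or `meanlog` for the lognormal")
      meanlog <- log(p95) - qnorm(0.95) * sdlog
    }
    out <- list(name = "lognormal", meanlog = meanlog, sdlog = sdlog)
  }
  class(out) <- "suv_distribution"
  out
}

#' Designed percentile of an `suv_distribution`
#' @param dist an [suv_distribution()].
#' @param p percentile in \[0, 100\].
#' @return the distribution's p-th percentile.
#' @export
designed_percentile <- function(dist, p) {
  switch(dist$name,
         constant  = dist$value,
         lognormal = exp(dist$meanlog + qnorm(p / 100) * dist$sdlog))
}

#' Specify a thoracic phantom
#'
#' @param grid_shape integer length-3, voxels per axis (all >= 16).
#' @param spacing_mm voxel size per axis in mm.
#' @param lung_suv_distribution an [suv_distribution()] for lung voxels.
#' @param include_cardiac_spillover,include_tumor,include_diaphragm_coldspot
#'   artifact switches.
#' @param include_airway build the central airway (default `TRUE`).
#' @param psf_fwhm_mm Gaussian width (FWHM, mm) applied to the high-uptake
#'   cardiac/tumor blobs, emulating PET resolution and producing spill-over
#'   into adjacent lung.  0 disables blurring.
#' @param dose_peak_gy peak of the dose field (Gy).
#' @param dose_sigma_mm per-axis Gaussian widths of the dose field.
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 80),
                         spacing_mm = c(3, 3, 3),
                         lung_suv_distribution = suv_distribution("lognormal", p95 = 1.2),
                         include_cardiac_spillover = FALSE,
                         include_tumor = FALSE,
                         include_diaphragm_coldspot = FALSE,
                         include_airway = TRUE,
                         psf_fwhm_mm = 7,
                         dose_peak_gy = 66,
                         dose_sigma_mm = c(45, 120, 45),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid too small to contain the thoracic structures: ",
         "grid_shape must be at least c(16, 16, 16)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive numbers")
  if (!inherits(lung_suv_distribution, "suv_distribution"))
    stop("lung_suv_distribution must be an suv_distribution()")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 lung_suv_distribution = lung_suv_distribution,
                 include_cardiac_spillover = isTRUE(include_cardiac_spillover),
                 include_tumor = isTRUE(include_tumor),
                 include_diaphragm_coldspot = isTRUE(include_diaphragm_coldspot),
                 include_airway = isTRUE(include_airway),
                 psf_fwhm_mm = psf_fwhm_mm,
                 dose_peak_gy = dose_peak_gy,
                 dose_sigma_mm = rep_len(as.numeric(dose_sigma_mm), 3),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# tissue values (HU / SUV) used by the generator
.HU_AIR <- -1000; .HU_LUNG <- -800; .HU_TISSUE <- 40; .HU_TUMOR <- 30
.SUV_AIR <- 0.02; .SUV_TISSUE <- 0.8
.SUV_HEART_EXTRA <- 3.2; .SUV_TUMOR_EXTRA <- 4.2
.COLDSPOT_FACTOR <- 0.55; .SPILL_TRUTH_SUV <- 0.05

#' Generate a thoracic phantom
#'
#' Builds CT (HU), PET (SUV) and dose (Gy) volumes on a common grid together
#' with ground truth: the exact lung mask (airway and tumor excluded), the
#' airway mask, per-artifact exclusion masks, and the true biomarker panel
#' computed from the clean, unblurred lung draws before any artifact is
#' applied.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `ct`, `pet`, `dose` ([image_volume()]s) and
#'   `truth` (lung/airway/artifact masks plus the true [uptake_summary()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  d <- spec$grid_shape; sp <- spec$spacing_mm
  ext <- d * sp; cx <- ext / 2
  # voxel-centre world coordinates
  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  zc <- (seq_len(d[3]) - 0.5) * sp[3]
  X <- array(xc, d)
  Y <- array(rep(yc, each = d[1]), d)
  Z <- array(rep(zc, each = d[1] * d[2]), d)

  ellipsoid <- function(c0, semi) {
    ((X - c0[1]) / semi[1])^2 + ((Y - c0[2]) / semi[2])^2 +
      ((Z - c0[3]) / semi[3])^2 <= 1
  }
  # body: elliptic cylinder through the full axial range
  body <- (((X - cx[1]) / (0.45 * ext[1]))^2 +
             ((Y - cx[2]) / (0.35 * ext[2]))^2) <= 1
  lung_semi <- c(0.17, 0.26, 0.40) * ext
  lung_zc <- 0.55 * ext[3]
  lungL <- ellipsoid(c(cx[1] - 0.21 * ext[1], cx[2], lung_zc), lung_semi)
  lungR <- ellipsoid(c(cx[1] + 0.21 * ext[1], cx[2], lung_zc), lung_semi)
  lungs <- lungL | lungR

  # central airway: trachea + main bronchi, kept >= 1 voxel clear of the
  # lungs so 26-connected labelling separates parenchyma from airway
  airway <- array(FALSE, d)
  if (spec$include_airway) {
    tr_r <- 0.030 * ext[1]
    carina_z <- 0.62 * ext[3]
    trachea <- (sqrt((X - cx[1])^2 + (Y - (cx[2] - 0.05 * ext[2]))^2) <= tr_r) &
      (Z >= carina_z)
    seg_cyl <- function(p0, p1, r) {
      dvec <- p1 - p0; L2 <- sum(dvec^2)
      t <- ((X - p0[1]) * dvec[1] + (Y - p0[2]) * dvec[2] +
              (Z - p0[3]) * dvec[3]) / L2
      t <- pmin(pmax(t, 0), 1)
      (X - p0[1] - t * dvec[1])^2 + (Y - p0[2] - t * dvec[2])^2 +
        (Z - p0[3] - t * dvec[3])^2 <= r^2
    }
    p0 <- c(cx[1], cx[2] - 0.05 * ext[2], carina_z)
    br_r <- 0.022 * ext[1]
    brL <- seg_cyl(p0, c(cx[1] - 0.14 * ext[1], cx[2], 0.52 * ext[3]), br_r)
    brR <- seg_cyl(p0, c(cx[1] + 0.14 * ext[1], cx[2], 0.52 * ext[3]), br_r)
    airway <- (trachea | brL | brR) & !dilate_mask(lungs, 1.01)
  }

  tumor <- array(FALSE, d)
  if (spec$include_tumor) {
    tumor <- ellipsoid(c(cx[1] + 0.19 * ext[1], cx[2], 0.58 * ext[3]),
                       rep(0.07 * ext[1], 3)) & lungs
  }
  lung_truth <- lungs & !airway & !tumor
  if (sum(lung_truth) < 1)
    stop("grid too small to contain the thoracic structures: ",
         "increase grid_shape (minimum c(16, 16, 16))")

  ## CT -----------------------------------------------------------------
  ct <- array(.HU_AIR, d)
  ct[body] <- .HU_TISSUE
  ct[lungs] <- .HU_LUNG
  ct[tumor] <- .HU_TUMOR
  ct[airway] <- .HU_AIR

  ## PET ----------------------------------------------------------------
  pet <- array(.SUV_AIR, d)
  pet[body] <- .SUV_TISSUE
  pet[airway] <- .SUV_AIR
  dist <- spec$lung_suv_distribution
  n_lung <- sum(lung_truth)
  clean <- switch(dist$name,
                  constant  = rep(dist$value, n_lung),
                  lognormal = rlnorm(n_lung, dist$meanlog, dist$sdlog))
  pet[lung_truth] <- clean
  truth_summary <- uptake_summary(clean, modality = "SUV")

  cold <- array(FALSE, d)
  if (spec$include_diaphragm_coldspot) {
    zmin_lung <- min(Z[lung_truth])
    cold <- lung_truth & (Z <= zmin_lung + 0.05 * ext[3])
    pet[cold] <- pet[cold] * .COLDSPOT_FACTOR
  }

  spill <- array(FALSE, d)
  blobs <- array(0, d)
  if (spec$include_cardiac_spillover) {
    heart <- ellipsoid(c(cx[1] - 0.10 * ext[1], cx[2] + 0.22 * ext[2],
                         0.45 * ext[3]),
                       rep(0.13 * ext[1], 3)) & body & !lungs
    hb <- array(0, d); hb[heart] <- .SUV_HEART_EXTRA
    hb <- gaussian_blur(hb, spec$psf_fwhm_mm, sp)
    spill <- lung_truth & (hb > .SPILL_TRUTH_SUV)
    blobs <- blobs + hb
  }
  tumor_excl <- array(FALSE, d)
  if (spec$include_tumor) {
    tb <- array(0, d); tb[tumor] <- .SUV_TUMOR_EXTRA
    tb <- gaussian_blur(tb, spec$psf_fwhm_mm, sp)
    tumor_excl <- lung_truth & (tb > .SPILL_TRUTH_SUV)
    blobs <- blobs + tb
  }
  pet <- pet + blobs

  ## dose ---------------------------------------------------------------
  dctr <- c(cx[1] + 0.15 * ext[1], cx[2], 0.55 * ext[3])
  sig <- spec$dose_sigma_mm
  dose <- spec$dose_peak_gy *
    exp(-((X - dctr[1])^2 / (2 * sig[1]^2) +
            (Y - dctr[2])^2 / (2 * sig[2]^2) +
            (Z - dctr[3])^2 / (2 * sig[3]^2)))

  mk <- function(m, step) binary_mask(m, reference = NULL,
                                      spacing_mm = sp, origin_mm = c(0, 0, 0),
                                      provenance = step)
  list(
    ct   = image_volume(ct, sp, "CT_HU"),
    pet  = image_volume(pet, sp, "PET_SUV"),
    dose = image_volume(dose, sp, "DOSE", unit = "Gy"),
    truth = list(
      lung_mask   = mk(lung_truth, "phantom truth lung (airway/tumor excluded)"),
      lung_plus_airway_mask = mk(lung_truth | airway, "phantom truth lung + airway"),
      airway_mask = mk(airway, "phantom truth airway"),
      artifact_masks = list(
        spill_over = mk(spill, "phantom truth cardiac spill-over"),
        tumor      = mk(tumor_excl, "phantom truth tumor spill"),
        cold_spot  = mk(cold, "phantom truth diaphragm cold-spot")),
      summary = truth_summary,
      spec = spec)
  )
}
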