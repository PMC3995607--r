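#' Acquisition metadata for SUV computation
#'
#' @param injected_dose_Bq injected activity at injection time, Bq (> 0).
#' @param injection_to_scan_min minutes from injection to scan start (>= 0).
#' @param body_weight_g patient body weight in grams (> 0).
#' @param half_life_min radionuclide half-life in minutes; default is the
#'   fluorine-18 half-life, 109.771 min.
#' @return an `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_dose_Bq, injection_to_scan_min,
                             body_weight_g, half_life_min = 109.771) {
  if (injected_dose_Bq <= 0) stop("injected_dose_Bq must be > 0")
  if (injection_to_scan_min < 0) stop("injection_to_scan_min must be >= 0")
  if (body_weight_g <= 0) stop("body_weight_g must be > 0")
  if (half_life_min <= 0) stop("half_life_min must be > 0")
  structure(list(injected_dose_Bq = injected_dose_Bq,
                 injection_to_scan_min = injection_to_scan_min,
                 body_weight_g = body_weight_g,
                 half_life_min = half_life_min),
            class = "acquisition_meta")
}

#' Radioactive decay factor between injection and scan
#'
#' The injected dose decays by `2^(-t / half_life)` over the uptake period;
#' the decay-corrected dose entering the SUV denominator is
#' `injected_dose_Bq * decay_factor(meta)`.
#'
#' @param meta an [acquisition_meta()].
#' @return unitless factor in (0, 1\].
#' @export
decay_factor <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  2^(-meta$injection_to_scan_min / meta$half_life_min)
}

#' Convert a PET activity-concentration volume to SUV
#'
#' Voxelwise `SUV = activity (Bq/mL) * body weight (g) / decay-corrected
#' injected dose (Bq)`.  A volume already tagged `PET_SUV` is rejected,
#' never silently rescaled.
#'
#' @param pet `image_volume` with modality `PET_ACTIVITY`.
#' @param meta an [acquisition_meta()].
#' @param input_unit `"Bq/mL"` (default) or `"kBq/mL"` (converted
#'   explicitly before applying the formula).
#' @return an `image_volume` tagged `PET_SUV` on the unchanged grid.
#' @export
activity_to_suv <- function(pet, meta, input_unit = c("Bq/mL", "kBq/mL")) {
  stopifnot(is_image_volume(pet), inherits(meta, "acquisition_meta"))
  input_unit <- match.arg(input_unit)
  if (pet$modality != "PET_ACTIVITY")
    stop("input modality is ", pet$modality,
         ", not PET_ACTIVITY; refusing to (re-)convert")
  act <- pet$data
  n_neg <- sum(act < 0)
  if (n_neg > 0)
    stop(n_neg, " negative activity voxel(s); activity must be >= 0")
  if (input_unit == "kBq/mL") act <- act * 1000
  suv <- act * meta$body_weight_g / (meta$injected_dose_Bq * decay_factor(meta))
  image_volume(suv, pet$spacing_mm, "PET_SUV", pet$origin_mm)
}
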