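#' Percentile of a collection of voxel values
#'
#' Linear interpolation between order statistics at rank
#' `1 + (p/100) * (n - 1)` (the type-7 estimator); `p = 0` returns the
#' minimum and `p = 100` the maximum.  The estimator type is exposed for
#' sensitivity checks.
#'
#' @param values nonempty numeric vector of finite values.
#' @param p percentile in \[0, 100\] (may be a vector).
#' @param type quantile estimator type passed to [stats::quantile()].
#' @return the percentile value(s).
#' @export
pctl <- function(values, p, type = 7) {
  if (length(values) == 0) stop("empty collection has no percentiles")
  if (any(!is.finite(values))) stop("values must all be finite")
  if (any(p < 0 | p > 100)) stop("p must lie in [0, 100]")
  unname(quantile(values, probs = p / 100, type = type, names = FALSE))
}

#' Biomarker panel of a set of values
#'
#' Mean, SD (n - 1 denominator), maximum and the 80th/90th/95th
#' percentiles.  A single value yields SD 0 with a warning.
#'
#' @param values nonempty numeric vector.
#' @param modality `"SUV"` or `"HU"` (unit label of the panel).
#' @param type percentile estimator type (see [pctl()]).
#' @return an `uptake_summary` with fields `mean`, `sd`, `max`, `p80`,
#'   `p90`, `p95`, `n_voxels`, `modality`.
#' @export
uptake_summary <- function(values, modality = c("SUV", "HU"), type = 7) {
  modality <- match.arg(modality)
  if (length(values) == 0) stop("empty collection; ROI must be nonempty")
  if (any(!is.finite(values))) stop("values must all be finite")
  if (length(values) == 1L) {
    warning("single-voxel ROI: sd is undefined, reporting 0")
    s <- 0
  } else s <- sd(values)
  q <- pctl(values, c(80, 90, 95), type = type)
  structure(list(modality = modality, mean = mean(values), sd = s,
                 max = max(values), p80 = q[1], p90 = q[2], p95 = q[3],
                 n_voxels = length(values)),
            class = "uptake_summary")
}

#' @export
print.uptake_summary <- function(x, ...) {
  cat(sprintf(
    "<uptake_summary %s> n=%d  mean=%.4g sd=%.4g max=%.4g  p80=%.4g p90=%.4g p95=%.4g\n",
    x$modality, x$n_voxels, x$mean, x$sd, x$max, x$p80, x$p90, x$p95))
  invisible(x)
}

#' @export
as.data.frame.uptake_summary <- function(x, ...) {
  data.frame(modality = x$modality, mean = x$mean, sd = x$sd, max = x$max,
             p80 = x$p80, p90 = x$p90, p95 = x$p95, n_voxels = x$n_voxels,
             stringsAsFactors = FALSE)
}

#' Summarise a volume over a lung ROI
#'
#' Computes the biomarker panel over exactly the ROI voxels of a SUV or HU
#' volume.  Dose volumes are refused (see [dose_metrics()]).
#'
#' @param volume `image_volume` with modality `PET_SUV` or `CT_HU`.
#' @param roi nonempty [binary_mask()] on the same grid.
#' @param type percentile estimator type.
#' @return an [uptake_summary()].
#' @export
summarize_roi <- function(volume, roi, type = 7) {
  stopifnot(is_image_volume(volume), inherits(roi, "binary_mask"))
  if (volume$modality == "DOSE")
    stop("dose volumes are summarised by dose_metrics(), not summarize_roi()")
  if (volume$modality == "PET_ACTIVITY")
    stop("convert activity to SUV first (activity_to_suv)")
  stopifnot_same_grid(volume, roi, "volume and ROI")
  if (roi$voxel_count == 0) stop("ROI is empty")
  uptake_summary(volume$data[roi$data],
                 modality = if (volume$modality == "CT_HU") "HU" else "SUV",
                 type = type)
}
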