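#' Lung dose-volume metrics
#'
#' Mean lung dose over the ROI and Vx: the percent of ROI volume receiving
#' strictly more than x Gy (or CGE), for x in `thresholds`.  The strict
#' inequality ("irradiated to above x") is pinned: a voxel at exactly the
#' threshold does not count.
#'
#' @param dose `image_volume` with modality `DOSE`, all voxels >= 0.
#' @param roi nonempty [binary_mask()] on the same grid.
#' @param thresholds dose thresholds in Gy/CGE (default 5, 10, 20, 30).
#' @return a `dose_metrics` object with fields `mld`, `v5` ... (named after
#'   the thresholds), `unit`, `n_voxels`.
#' @export
dose_metrics <- function(dose, roi, thresholds = c(5, 10, 20, 30)) {
  stopifnot(is_image_volume(dose), inherits(roi, "binary_mask"))
  if (dose$modality != "DOSE") stop("dose_metrics needs a DOSE volume")
  stopifnot_same_grid(dose, roi, "dose and ROI")
  if (roi$voxel_count == 0) stop("ROI is empty")
  v <- dose$data[roi$data]
  n_neg <- sum(v < 0)
  if (n_neg > 0) stop(n_neg, " negative dose voxel(s) in ROI")
  vx <- vapply(thresholds, function(t) 100 * mean(v > t), numeric(1))
  names(vx) <- paste0("v", thresholds)
  structure(c(list(mld = mean(v)), as.list(vx),
              list(unit = if (is.null(dose$unit)) "Gy" else dose$unit,
                   thresholds = thresholds, n_voxels = length(v))),
            class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  vx <- unlist(x[paste0("v", x$thresholds)])
  cat(sprintf("<dose_metrics> MLD %.3g %s;  %s\n", x$mld, x$unit,
              paste(sprintf("V%g=%.1f%%", x$thresholds, vx), collapse = "  ")))
  invisible(x)
}

#' @export
as.data.frame.dose_metrics <- function(x, ...) {
  out <- data.frame(mld = x$mld)
  for (t in x$thresholds) out[[paste0("v", t)]] <- x[[paste0("v", t)]]
  out$dose_unit <- x$unit
  out
}

#' Convert a proton dose grid to Cobalt Gray Equivalents
#'
#' Voxelwise multiplication by the relative biological effectiveness
#' factor; the unit tag becomes `"CGE"`.  Converting a grid already tagged
#' CGE is an error (never applied twice).
#'
#' @param dose `image_volume` with modality `DOSE` in proton Gy.
#' @param rbe relative biological effectiveness (> 0; default 1.1).
#' @return an `image_volume` with unit `"CGE"`.
#' @export
to_cge <- function(dose, rbe = 1.1) {
  stopifnot(is_image_volume(dose))
  if (dose$modality != "DOSE") stop("to_cge needs a DOSE volume")
  if (rbe <= 0) stop("rbe must be > 0")
  if (identical(dose$unit, "CGE"))
    stop("dose is already in CGE; refusing to apply the RBE factor twice")
  image_volume(dose$data * rbe, dose$spacing_mm, "DOSE",
               dose$origin_mm, unit = "CGE")
}
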