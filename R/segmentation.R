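# Lung ROI construction: parenchyma by histogram (Otsu) thresholding of the
# CT, central airway removal by connectivity, and subtraction of manually
# supplied artifact exclusion regions.  Everything here is deterministic.

#' Otsu threshold of a numeric sample
#'
#' Maximises between-class variance on a fixed-width histogram of the values
#' clipped to `clip`.  Used to find the valley between the air/lung mode and
#' the soft-tissue mode of a thoracic HU histogram.
#'
#' @param x numeric values.
#' @param clip length-2 clipping range applied before binning.
#' @param nbins histogram bins.
#' @return the threshold (a bin edge).
#' @export
otsu_threshold <- function(x, clip = c(-1000, 200), nbins = 256) {
  x <- pmin(pmax(x[is.finite(x)], clip[1]), clip[2])
  edges <- seq(clip[1], clip[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  cw <- cumsum(w); cm <- cumsum(w * mids); mt <- cm[nbins]
  # between-class variance for every split point
  denom <- cw * (1 - cw)
  bcv <- ifelse(denom > 0, (mt * cw - cm)^2 / denom, 0)
  edges[which.max(bcv[-nbins]) + 1]
}

.LATERAL_BORDER_AXES <- 1:2  # x and y faces; cranio-caudal faces don't count

touches_lateral_border <- function(labels) {
  d <- dim(labels)
  edge <- c(labels[1, , ], labels[d[1], , ], labels[, 1, ], labels[, d[2], ])
  sort(unique(edge[edge > 0]))
}

#' Segment the lung parenchyma from a CT volume
#'
#' Thresholds the HU histogram in the valley between the air/lung and
#' soft-tissue modes (Otsu on values clipped to \[-1000, 200\]; fixed
#' fallback -400 HU if the valley is implausible), discards components
#' touching the lateral image border (exterior air), keeps the two largest
#' 26-connected components and closes them with a 2-voxel ball to fill
#' vessels.
#'
#' @param ct `image_volume` with modality `CT_HU`.
#' @param threshold optional manual HU threshold overriding the automatic
#'   choice.
#' @return a [binary_mask()] with provenance.
#' @export
segment_lung_parenchyma <- function(ct, threshold = NULL) {
  stopifnot(is_image_volume(ct))
  if (ct$modality != "CT_HU") stop("lung segmentation needs a CT_HU volume")
  v <- ct$data
  if (!any(v < -500) || !any(v > -200))
    stop("HU range implausible for thoracic CT (need voxels < -500 and > -200); ",
         "is the volume calibrated?")
  prov <- character()
  if (is.null(threshold)) {
    threshold <- otsu_threshold(v)
    if (threshold < -900 || threshold > -200) {
      threshold <- -400
      warning("Otsu valley implausible; using fallback threshold -400 HU")
      prov <- c(prov, "threshold: fallback -400 HU")
    } else {
      prov <- c(prov, sprintf("threshold: Otsu %.1f HU", threshold))
    }
  } else {
    prov <- c(prov, sprintf("threshold: manual %.1f HU", threshold))
  }
  below <- v < threshold
  labs <- label_components(below, connectivity = 26)
  drop <- touches_lateral_border(labs)
  sizes <- tabulate(labs)
  if (length(drop)) sizes[drop] <- 0L
  keep <- order(sizes, decreasing = TRUE)[1:2]
  if (length(which(sizes > 0)) < 2 || any(sizes[keep] == 0))
    stop("fewer than two candidate lung components below ", round(threshold),
         " HU; consider overriding with segment_lung_parenchyma(ct, threshold = ...)")
  mask <- array(labs %in% keep, dim(v))
  prov <- c(prov,
            sprintf("components: kept 2 largest of %d (sizes %d, %d)",
                    sum(sizes > 0), sizes[keep][1], sizes[keep][2]),
            "morphology: closing, ball radius 2 voxels")
  mask <- close_mask(mask, 2)
  binary_mask(mask, reference = ct, provenance = prov)
}

#' Extract the central airway by region growing
#'
#' Seeds at the most superior 6-connected cluster of voxels below -950 HU
#' inside the medial third of the axial plane (the trachea), grows over all
#' 6-connected sub--950-HU voxels, and dilates the grown region by one
#' voxel.  If no seed is found an empty mask is returned with a warning,
#' not an error.
#'
#' @param ct `image_volume` with modality `CT_HU`.
#' @param lung_plus_airway nonempty [binary_mask()] from
#'   [segment_lung_parenchyma()] (used for grid validation).
#' @return a [binary_mask()] of the airway.
#' @export
extract_central_airway <- function(ct, lung_plus_airway) {
  stopifnot(is_image_volume(ct), inherits(lung_plus_airway, "binary_mask"))
  if (ct$modality != "CT_HU") stop("airway extraction needs a CT_HU volume")
  stopifnot_same_grid(ct, lung_plus_airway, "CT and lung mask")
  if (lung_plus_airway$voxel_count == 0) stop("lung mask is empty")
  d <- dim(ct$data)
  cand <- ct$data < -950
  med <- array(FALSE, d)
  ix <- seq(ceiling(d[1] / 3) + 1, floor(2 * d[1] / 3))
  iy <- seq(ceiling(d[2] / 3) + 1, floor(2 * d[2] / 3))
  med[ix, iy, ] <- TRUE
  seeds <- cand & med
  empty <- binary_mask(array(FALSE, d), reference = ct,
                       provenance = "airway: no seed found")
  if (!any(seeds)) {
    warning("no airway seed voxel (< -950 HU in the medial third); ",
            "returning an empty airway mask")
    return(empty)
  }
  labs <- label_components(cand, connectivity = 6)
  drop <- touches_lateral_border(labs)
  seed_labs <- setdiff(unique(labs[seeds]), c(0L, drop))
  if (!length(seed_labs)) {
    warning("medial sub--950-HU voxels all belong to exterior air; ",
            "returning an empty airway mask")
    return(empty)
  }
  # most-superior cluster: the component reaching the greatest z
  kz <- rep(seq_len(d[3]), each = d[1] * d[2])
  topz <- vapply(seed_labs, function(l) max(kz[labs == l]), numeric(1))
  grown <- array(labs == seed_labs[which.max(topz)], d)
  grown <- dilate_mask(grown, 1)
  binary_mask(grown, reference = ct,
              provenance = sprintf(
                "airway: 6-connected growth from superior medial seed, %d voxels after 1-voxel dilation",
                sum(grown)))
}

#' An artifact exclusion region
#'
#' @param mask a [binary_mask()] covering the voxels to exclude.
#' @param label one of `"spill_over"`, `"cold_spot"`, `"tumor"`.
#' @return an `exclusion_roi`.
#' @export
exclusion_roi <- function(mask, label = c("spill_over", "cold_spot", "tumor")) {
  stopifnot(inherits(mask, "binary_mask"))
  label <- match.arg(label)
  structure(list(mask = mask, label = label), class = "exclusion_roi")
}

#' Assemble the final lung ROI
#'
#' `ROI = parenchyma - airway - union(exclusions)`.  Each subtraction and
#' its voxel delta is recorded in the provenance.
#'
#' @param parenchyma [binary_mask()] from [segment_lung_parenchyma()].
#' @param airway [binary_mask()] from [extract_central_airway()] (may be
#'   empty).
#' @param exclusions list of [exclusion_roi()] objects.
#' @return a [binary_mask()]; error if the result is empty.
#' @export
finalize_lung_roi <- function(parenchyma, airway = NULL, exclusions = list()) {
  stopifnot(inherits(parenchyma, "binary_mask"))
  if (inherits(exclusions, "exclusion_roi")) exclusions <- list(exclusions)
  roi <- parenchyma$data
  prov <- c(parenchyma$provenance,
            sprintf("roi: parenchyma %d voxels", sum(roi)))
  if (!is.null(airway)) {
    stopifnot(inherits(airway, "binary_mask"))
    stopifnot_same_grid(parenchyma, airway, "parenchyma and airway masks")
    before <- sum(roi)
    roi <- roi & !airway$data
    prov <- c(prov, sprintf("roi: minus airway (-%d voxels)", before - sum(roi)))
  }
  for (ex in exclusions) {
    if (!inherits(ex, "exclusion_roi"))
      stop("exclusions must be exclusion_roi objects")
    stopifnot_same_grid(parenchyma, ex$mask, "parenchyma and exclusion masks")
    before <- sum(roi)
    roi <- roi & !ex$mask$data
    prov <- c(prov, sprintf("roi: minus %s exclusion (-%d voxels)",
                            ex$label, before - sum(roi)))
  }
  if (!any(roi))
    stop("final lung ROI is empty after subtracting airway/exclusions")
  binary_mask(roi, spacing_mm = parenchyma$spacing_mm,
              origin_mm = parenchyma$origin_mm, provenance = prov)
}
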