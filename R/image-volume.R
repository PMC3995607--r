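#' Recognised image modalities
#'
#' Every [image_volume()] carries one of these tags: `"CT_HU"` (CT in
#' Hounsfield units), `"PET_ACTIVITY"` (PET activity concentration, Bq/mL),
#' `"PET_SUV"` (PET as standard uptake values, dimensionless) or `"DOSE"`
#' (radiotherapy dose, Gy or CGE).
#' @export
MODALITIES <- c("CT_HU", "PET_ACTIVITY", "PET_SUV", "DOSE")

#' Create a 3-D image volume
#'
#' A minimal voxel-grid container: a numeric 3-D array plus per-axis voxel
#' spacing, a world-space origin, and a modality tag.  World position of the
#' centre of 0-based voxel index `v` is `origin + v * spacing`.
#'
#' @param data numeric 3-D array of voxel values.
#' @param spacing_mm numeric length-3, voxel size per axis in mm (all > 0).
#' @param modality one of [MODALITIES].
#' @param origin_mm numeric length-3 world position of voxel (0,0,0), mm.
#' @param unit value unit label (e.g. `"Gy"`, `"CGE"`, `"Bq/mL"`); optional.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm, modality,
                         origin_mm = c(0, 0, 0), unit = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive numbers")
  modality <- match.arg(modality, MODALITIES)
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("`origin_mm` must have length 3")
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, modality = modality, unit = unit),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels @ %s mm%s\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              if (is.null(x$unit)) "" else paste0("  [", x$unit, "]")))
  v <- x$data
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Test whether two volumes/masks share the same voxel grid
#' @param a,b `image_volume` or `binary_mask` objects.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(dim(grid_of(a)$dim), dim(grid_of(b)$dim))) &&
    identical(grid_of(a)$dim, grid_of(b)$dim) &&
    isTRUE(all.equal(grid_of(a)$spacing, grid_of(b)$spacing,
                     tolerance = 1e-8)) &&
    isTRUE(all.equal(grid_of(a)$origin, grid_of(b)$origin,
                     tolerance = 1e-8))
}

grid_of <- function(x) {
  list(dim = dim(x$data), spacing = x$spacing_mm, origin = x$origin_mm)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not grid-aligned; resample first (see resample_to_grid)",
                 what))
  invisible(TRUE)
}

#' Create a binary mask on an image grid
#'
#' @param data logical 3-D array.
#' @param spacing_mm,origin_mm grid geometry (taken from `reference` if given).
#' @param reference optional `image_volume` or `binary_mask` supplying geometry.
#' @param provenance character vector of processing steps applied so far.
#' @return an object of class `binary_mask` with a `voxel_count` field.
#' @export
binary_mask <- function(data, spacing_mm = NULL, origin_mm = NULL,
                        reference = NULL, provenance = character()) {
  if (!is.null(reference)) {
    g <- grid_of(reference)
    spacing_mm <- g$spacing; origin_mm <- g$origin
    if (!identical(dim(data), g$dim))
      stop("mask shape does not match the reference grid")
  }
  if (is.null(origin_mm)) origin_mm <- c(0, 0, 0)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3-D array")
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 voxel_count = sum(data), provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d grid, %d voxels set\n",
              d[1], d[2], d[3], x$voxel_count))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b `binary_mask` objects (or logical arrays) on the same grid.
#' @return Dice coefficient in \[0, 1\]; 1 for two empty masks.
#' @export
dice <- function(a, b) {
  am <- if (inherits(a, "binary_mask")) a$data else a
  bm <- if (inherits(b, "binary_mask")) b$data else b
  if (!identical(dim(am), dim(bm))) stop("masks are on different grids")
  na <- sum(am); nb <- sum(bm)
  if (na + nb == 0) return(1)
  2 * sum(am & bm) / (na + nb)
}

#' Resample a volume onto the grid of a reference volume (trilinear)
#'
#' Values are interpolated trilinearly in world space; target voxels falling
#' outside the source grid take the nearest edge value (clamped).
#'
#' @param vol `image_volume` to resample.
#' @param ref `image_volume` (or `binary_mask`) defining the target grid.
#' @return an `image_volume` on the grid of `ref`.
#' @export
resample_to_grid <- function(vol, ref) {
  if (same_grid(vol, ref)) return(vol)
  dr <- grid_of(ref)$dim; sr <- grid_of(ref)$spacing; orr <- grid_of(ref)$origin
  ds <- dim(vol$data); ss <- vol$spacing_mm; os <- vol$origin_mm
  # world coordinates of target voxel centres, converted to source index space
  ax <- lapply(1:3, function(k) {
    w <- orr[k] + (seq_len(dr[k]) - 1) * sr[k]
    (w - os[k]) / ss[k]              # 0-based fractional source index
  })
  n <- prod(dr)
  gx <- rep(ax[[1]], times = dr[2] * dr[3])
  gy <- rep(rep(ax[[2]], each = dr[1]), times = dr[3])
  gz <- rep(ax[[3]], each = dr[1] * dr[2])
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  gx <- clamp(gx, ds[1] - 1); gy <- clamp(gy, ds[2] - 1); gz <- clamp(gz, ds[3] - 1)
  x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
  x1 <- pmin(x0 + 1, ds[1] - 1); y1 <- pmin(y0 + 1, ds[2] - 1)
  z1 <- pmin(z0 + 1, ds[3] - 1)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  at <- function(i, j, k) vol$data[1 + i + ds[1] * (j + ds[2] * k)]
  v <-
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    at(x1, y1, z0) * fx       * fy       * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx       * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy       * fz +
    at(x1, y1, z1) * fx       * fy       * fz
  image_volume(array(v, dr), sr, vol$modality, orr, vol$unit)
}

#' Write / read a volume as NIfTI with a JSON sidecar
#'
#' The voxel array and spacing go into the NIfTI file; modality, unit and
#' origin are stored in `<path minus extension>.json` so that round-trips
#' preserve the full object.
#'
#' @param vol `image_volume` (or `binary_mask`, written as uint8).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `write_volume`: the path, invisibly. `read_volume`: the object.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "binary_mask")
  arr <- if (is_mask) array(as.integer(vol$data), dim(vol$data)) else vol$data
  img <- RNifti::asNifti(arr, reference = NULL)
  img <- RNifti::`pixdim<-`(img, vol$spacing_mm)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  meta <- list(
    modality = if (is_mask) "MASK" else vol$modality,
    unit = if (is_mask) NULL else vol$unit,
    origin_mm = vol$origin_mm,
    spacing_mm = vol$spacing_mm
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  arr <- array(as.vector(img), dim(img))
  if (identical(meta$modality, "MASK")) {
    binary_mask(arr > 0, spacing_mm = meta$spacing_mm,
                origin_mm = meta$origin_mm)
  } else {
    image_volume(arr, meta$spacing_mm, meta$modality,
                 meta$origin_mm, meta$unit)
  }
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}
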