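# Low-level 3-D morphology on logical arrays.  Connected components and
# Gaussian blurring are C++ (see src/petrp.cpp); dilation/erosion are done
# by shifted-copy union, which is fast for the small ball radii used here.

neighbourhood_offsets <- function(connectivity = c(26, 6)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == "6") g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

ball_offsets <- function(radius_vox) {
  r <- ceiling(radius_vox)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g <- g[rowSums(g^2) <= radius_vox^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

# Label 26- or 6-connected components; returns integer array, 0 = background.
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  .cc_label_cpp(as.logical(mask), as.integer(dim(mask)),
                neighbourhood_offsets(connectivity))
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- seq_len(d[k] - o) + o; src[[k]] <- seq_len(d[k] - o) }
    else        { dst[[k]] <- seq_len(d[k] + o);     src[[k]] <- seq_len(d[k] + o) - o }
    if (length(dst[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_mask <- function(mask, radius_vox) {
  offs <- ball_offsets(radius_vox)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) out <- out | shift_array(mask, offs[i, ])
  out
}

erode_mask <- function(mask, radius_vox) !dilate_mask(!mask, radius_vox)

close_mask <- function(mask, radius_vox) {
  erode_mask(dilate_mask(mask, radius_vox), radius_vox)
}

# Separable Gaussian blur of a 3-D numeric array; fwhm_mm may be scalar or
# per-axis.  fwhm 0 is the identity.
gaussian_blur <- function(arr, fwhm_mm, spacing_mm) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L, all(fwhm_mm >= 0))
  fwhm_mm <- rep_len(fwhm_mm, 3)
  out <- arr
  for (ax in 1:3) {
    sigma_vox <- (fwhm_mm[ax] / 2.354820045) / spacing_mm[ax]
    if (sigma_vox <= 0) next
    half <- max(1L, ceiling(3 * sigma_vox))
    k <- dnorm(seq(-half, half), sd = sigma_vox)
    k <- k / sum(k)
    out <- .convolve_axis_cpp(out, as.integer(dim(arr)), k, as.integer(ax))
  }
  out
}
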