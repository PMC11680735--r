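# Threshold-based lung/airway segmentation with morphological cleanup.

#' Lung mask container
#'
#' Integer labels per voxel: 0 background, 1 lung parenchyma, 2 airway.
#' Airway voxels are excluded from all downstream lung statistics.
#'
#' @param labels integer array with values in \{0, 1, 2\}.
#' @param spacing voxel spacing, mm.
#' @return object of class `lung_mask`.
#' @export
lung_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (!all(labels %in% 0:2)) stop("labels must be in {0, 1, 2}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing[1:3])),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  v <- mask_volumes(x)
  cat(sprintf("<lung_mask> %s voxels; lung %.1f mL, airway %.1f mL\n",
              paste(dim(x$labels), collapse = "x"), v["tlv_ml"],
              v["airway_ml"]))
  invisible(x)
}

# 3D binary erosion/dilation with a cubic structuring element of given radius,
# via run of +/-1 shifts per axis (separable for the cube).
shift_arr <- function(a, axis, by) {
  d <- dim(a); idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (by > 0) { dst[[axis]] <- (1 + by):d[axis]; src[[axis]] <- 1:(d[axis] - by) }
  else if (by < 0) { dst[[axis]] <- 1:(d[axis] + by); src[[axis]] <- (1 - by):d[axis] }
  out <- array(FALSE, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

morph_cube <- function(mask, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (b in seq_len(radius)) {
      s1 <- shift_arr(out, axis, b); s2 <- shift_arr(out, axis, -b)
      acc <- if (op == "erode") acc & s1 & s2 else acc | s1 | s2
    }
    out <- acc
  }
  out
}

morph_open <- function(m, r) morph_cube(morph_cube(m, r, "erode"), r, "dilate")
morph_close <- function(m, r) morph_cube(morph_cube(m, r, "dilate"), r, "erode")

#' Otsu-threshold lung segmentation
#'
#' Computes a global Otsu threshold on the pooled volume intensities, scales
#' it by `threshold_scale`, keeps voxels above it, applies morphological
#' opening then closing with a cubic element of edge length `element_size`
#' voxels (the default 1 is a single-voxel element, i.e. no morphological
#' smoothing), and retains the two largest connected components (the two
#' lungs; a single component holding at least 60% of the foreground is
#' accepted alone, covering merged lungs).
#'
#' @param vol a real-valued [image_volume].
#' @param threshold_scale multiplier on the Otsu threshold (default 1).
#' @param element_size structuring-element edge length in voxels (default 1).
#' @return a [lung_mask] (labels 0/1).
#' @export
otsu_lung_mask <- function(vol, threshold_scale = 1, element_size = 1) {
  stopifnot(inherits(vol, "image_volume"))
  x <- vol$data
  if (is.complex(x)) stop("segmentation needs a real-valued volume")
  rng <- range(x)
  if (diff(rng) == 0) stop("constant image: Otsu threshold undefined")
  xn <- (x - rng[1]) / diff(rng)
  thr_n <- EBImage::otsu(EBImage::Image(matrix(xn, nrow = dim(x)[1])),
                         range = c(0, 1))
  thr <- (rng[1] + thr_n * diff(rng)) * threshold_scale
  fg <- x > thr
  if (!any(fg)) {
    warning("threshold above all intensities: empty mask", call. = FALSE)
    return(lung_mask(array(0L, dim(x)), vol$spacing))
  }
  radius <- (element_size - 1) %/% 2
  if (radius > 0) {
    fg <- morph_close(morph_open(fg, radius), radius)
  }
  lab <- cc_label_3d(as.logical(fg), dim(x), 6L)
  ncomp <- attr(lab, "n_components")
  keep <- array(FALSE, dim(x))
  if (ncomp > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    ord <- order(sizes, decreasing = TRUE)
    if (sizes[ord[1]] >= 0.6 * sum(sizes)) keep <- lab == ord[1]
    else keep <- array(lab %in% ord[seq_len(min(2, ncomp))], dim(x))
  }
  out <- array(0L, dim(x)); out[keep] <- 1L
  if (!any(out == 1L)) warning("empty lung mask after cleanup", call. = FALSE)
  lung_mask(out, vol$spacing)
}

#' Relabel airways inside a lung mask
#'
#' Grows a connected high-intensity tube from a seed voxel (default: the
#' brightest voxel in the superior-central region of the volume) and
#' relabels it 2 so downstream lung statistics can exclude it.
#'
#' @param vol the intensity [image_volume].
#' @param mask a [lung_mask].
#' @param seed_voxel optional `c(x, y, z)` seed; must lie inside the volume.
#' @param intensity_frac voxels above this fraction of the in-mask robust
#'   maximum are airway candidates.
#' @return the updated [lung_mask].
#' @export
remove_airways <- function(vol, mask, seed_voxel = NULL, intensity_frac = 0.9) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "lung_mask"))
  x <- vol$data; d <- dim(x)
  if (!any(mask$labels > 0L)) stop("mask has no lung voxels")
  if (is.null(seed_voxel)) {
    # superior-central search region: central third in x and z, upper 40% in y
    xi <- slice.index(x, 1); yi <- slice.index(x, 2); zi <- slice.index(x, 3)
    region <- xi > d[1] / 3 & xi <= 2 * d[1] / 3 & yi <= 0.4 * d[2] &
      zi > d[3] / 3 & zi <= 2 * d[3] / 3
    if (!any(region)) region <- array(TRUE, d)
    cand <- which(region)
    seed_idx <- cand[which.max(x[cand])]
  } else {
    sv <- round(seed_voxel)
    if (any(sv < 1) || any(sv > d)) stop("seed outside volume")
    if (x[sv[1], sv[2], sv[3]] <= 0 ||
        x[sv[1], sv[2], sv[3]] < 0.1 * max(x))
      stop("seed voxel lies in background")
    seed_idx <- sv[1] + d[1] * ((sv[2] - 1) + d[2] * (sv[3] - 1))
  }
  inl <- mask$labels > 0L
  thr <- intensity_frac * stats::quantile(x, 0.999, names = FALSE)
  if (thr < 1.2 * mean(x[inl])) return(mask)  # no distinctly bright airway
  high <- x >= thr
  if (!high[seed_idx]) return(mask)
  lab <- cc_label_3d(as.logical(high), d, 26L)
  tube <- lab == lab[seed_idx]
  if (sum(tube) > 0.25 * sum(inl)) {
    warning("bright region from seed is not tube-like; mask unchanged",
            call. = FALSE)
    return(mask)
  }
  out <- mask$labels
  out[tube] <- 2L
  lung_mask(out, mask$spacing)
}

#' Lung and airway volumes from a mask
#'
#' @param mask a [lung_mask].
#' @param spacing voxel spacing mm; defaults to the mask's.
#' @return named vector `c(tlv_ml, airway_ml)` — total lung volume (label 1)
#'   and airway volume (label 2) in mL.
#' @export
mask_volumes <- function(mask, spacing = mask$spacing) {
  vox_ml <- prod(spacing) / 1000
  c(tlv_ml = sum(mask$labels == 1L) * vox_ml,
    airway_ml = sum(mask$labels == 2L) * vox_ml)
}
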