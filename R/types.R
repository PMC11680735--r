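#' Image volume container
#'
#' A light container for a reconstructed 3D (or 4D) voxel array together with
#' the acquisition geometry the pipeline needs: voxel spacing in mm, the
#' acquisition plane, and whether the data are complex-valued. The plane is
#' recorded from the acquisition and is never resampled or reoriented by any
#' reader or processing step.
#'
#' @param data numeric or complex array with 3 or 4 dimensions.
#' @param spacing numeric vector of per-axis voxel spacing in mm (first three
#'   axes). All entries must be positive.
#' @param plane acquisition plane, one of `"coronal"`, `"axial"`, `"sagittal"`.
#' @param is_complex logical; defaults to `is.complex(data)`.
#' @param meta named list of free-form acquisition tags.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), plane = "coronal",
                         is_complex = is.complex(data), meta = list()) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) < 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  plane <- match.arg(plane, c("coronal", "axial", "sagittal"))
  if (any(!is.finite(Re(data))) || (is.complex(data) && any(!is.finite(Im(data)))))
    stop("voxel data must be finite")
  structure(list(data = data, spacing = spacing[1:3], plane = plane,
                 is_complex = isTRUE(is_complex), meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, plane %s%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$plane, if (x$is_complex) ", complex" else ""))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Raw acquisition container
#'
#' Holds unreconstructed data: an FID train from the calibration sequence, 2D
#' Cartesian k-space, or interleaved 3D radial k-space with its trajectory.
#' Each excitation carries a `ppm_offset` tag giving the chemical-shift offset
#' of the excitation centre, which is how gas (0 ppm) and dissolved-phase
#' (about 218 ppm) excitations are told apart.
#'
#' @param kind `"fid_train"`, `"cartesian2d"` or `"radial3d"`.
#' @param samples complex matrix, excitations x readout points.
#' @param trajectory for `radial3d` only: array `c(3, readout, excitations)`
#'   of normalized k-space coordinates in cycles/FOV, magnitudes <= 0.5.
#' @param dwell_s readout dwell time in seconds (> 0).
#' @param tr_ms,te_ms repetition and echo time in ms.
#' @param prescribed_flip_deg prescribed flip angle in degrees.
#' @param center_freq_hz transmitter centre frequency in Hz.
#' @param ppm_offset numeric vector (length 1 or one per excitation) of the
#'   excitation-centre chemical-shift offset in ppm.
#' @return an object of class `raw_acquisition`.
#' @export
raw_acquisition <- function(kind, samples, trajectory = NULL, dwell_s,
                            tr_ms = NA_real_, te_ms = NA_real_,
                            prescribed_flip_deg = NA_real_,
                            center_freq_hz = NA_real_, ppm_offset = 0) {
  kind <- match.arg(kind, c("fid_train", "cartesian2d", "radial3d"))
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.complex(samples)) storage.mode(samples) <- "complex"
  if (nrow(samples) < 1L) stop("at least one excitation required")
  if (!is.numeric(dwell_s) || dwell_s <= 0) stop("`dwell_s` must be > 0")
  if (kind == "radial3d") {
    if (is.null(trajectory)) stop("radial3d acquisitions need a trajectory")
    d <- dim(trajectory)
    if (length(d) != 3L || d[1] != 3L || d[2] != ncol(samples) || d[3] != nrow(samples))
      stop("trajectory must be a 3 x readout x excitations array matching `samples`")
    if (max(abs(trajectory)) > 0.5 + 1e-9)
      stop("normalized trajectory magnitudes must be <= 0.5")
  }
  ppm_offset <- rep_len(as.numeric(ppm_offset), nrow(samples))
  structure(list(kind = kind, samples = samples, trajectory = trajectory,
                 dwell_s = dwell_s, tr_ms = tr_ms, te_ms = te_ms,
                 prescribed_flip_deg = prescribed_flip_deg,
                 center_freq_hz = center_freq_hz, ppm_offset = ppm_offset),
            class = "raw_acquisition")
}

#' @export
print.raw_acquisition <- function(x, ...) {
  cat(sprintf("<raw_acquisition> kind=%s, %d excitations x %d points, dwell %.3g us\n",
              x$kind, nrow(x$samples), ncol(x$samples), x$dwell_s * 1e6))
  tab <- table(x$ppm_offset)
  cat("  ppm offsets:", paste(sprintf("%s ppm x%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Healthy reference distribution
#'
#' Mean and SD of a quantity in healthy subjects, used to place linear-binning
#' thresholds at mu +/- k sigma. For ADC the reference may be parameterized by
#' age through a linear model for both moments.
#'
#' @param mu,sigma reference mean and SD (sigma > 0).
#' @param age_model optional named list `(slope_mu, intercept_mu, slope_sigma,
#'   intercept_sigma)` for age-dependent references.
#' @return an object of class `healthy_reference`.
#' @export
healthy_reference <- function(mu, sigma, age_model = NULL) {
  if (!is.null(age_model)) {
    need <- c("slope_mu", "intercept_mu", "slope_sigma", "intercept_sigma")
    if (!all(need %in% names(age_model)))
      stop("age_model needs fields: ", paste(need, collapse = ", "))
  } else if (sigma <= 0) stop("`sigma` must be > 0")
  structure(list(mu = mu, sigma = sigma, age_model = age_model),
            class = "healthy_reference")
}

#' @export
print.healthy_reference <- function(x, ...) {
  cat(sprintf("<healthy_reference> mu = %g, sigma = %g%s\n", x$mu, x$sigma,
              if (!is.null(x$age_model)) " (age model attached)" else ""))
  invisible(x)
}

# shared 6-bin linear binning used by ventilation, diffusion and gas exchange;
# edges mu-2s, mu-s, mu, mu+s, mu+2s, optionally extended high-side (membrane).
linear_bin_map <- function(values, mask, mu, sigma, n_high_extra = 0L,
                           clip_zero = TRUE) {
  ks <- c(-2, -1, 0, 1, 2, if (n_high_extra > 0) seq_len(n_high_extra) + 2)
  edges <- mu + ks * sigma
  if (clip_zero && edges[1] <= 0) {
    warning("lower bin edges at or below zero were clipped", call. = FALSE)
    edges <- pmax(edges, .Machine$double.eps * seq_along(edges))
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  labels <- array(0L, dim(mask))
  inl <- which(mask)
  labels[inl] <- findInterval(values[inl], edges) + 1L
  nbin <- length(edges) + 1L
  pct <- 100 * tabulate(labels[inl], nbins = nbin) / length(inl)
  nm <- if (n_high_extra == 0)
    c("defect", "low", "normal1", "normal2", "high1", "high2")
  else c("defect", "low", "normal1", "normal2",
         paste0("high", seq_len(2 + n_high_extra)))
  structure(list(labels = labels, bin_edges = edges, bin_names = nm,
                 percentages = stats::setNames(pct, nm)),
            class = "bin_map")
}

#' @export
print.bin_map <- function(x, ...) {
  cat("<bin_map>", length(x$bin_names), "bins; percentages of mask:\n")
  print(round(x$percentages, 2))
  invisible(x)
}
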