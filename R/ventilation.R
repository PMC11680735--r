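# Ventilation post-processing: SNR, bias correction, three VDP algorithms,
# defect distribution index, gray-level run-length texture.

mask_lung <- function(mask) mask$labels == 1L

#' Signal-to-noise ratio with Rayleigh background correction
#'
#' The background of a magnitude image is Rayleigh-distributed, so the
#' measured background SD underestimates the underlying complex noise SD;
#' the corrected noise is `sigma_bg = sigma_m / sqrt(2 - pi/2)`. SNR is
#' `S_lung / sigma_bg`, or `(S_lung - S_bg) / sigma_bg` with
#' `variant = "bgsub"` (the gas-exchange convention).
#'
#' @param vol magnitude [image_volume].
#' @param mask a [lung_mask]; the background is label 0 eroded away from the
#'   lungs (and airways) by `background_margin` voxels.
#' @param background_margin dilation radius separating background from lung.
#' @param variant `"ratio"` or `"bgsub"`.
#' @return object of class `snr_report`: `s_lung`, `s_bg`, `sigma_m`,
#'   `sigma_bg`, `snr`, `n_background`.
#' @export
compute_snr <- function(vol, mask, background_margin = 3,
                        variant = c("ratio", "bgsub")) {
  variant <- match.arg(variant)
  x <- vol$data
  if (is.complex(x)) x <- Mod(x)
  inl <- mask_lung(mask)
  near <- morph_cube(mask$labels > 0L, background_margin, "dilate")
  bg <- !near
  if (!any(bg)) stop("no background voxels outside the dilated mask")
  if (sum(bg) < 100)
    warning("fewer than 100 background voxels; sigma estimate unstable",
            call. = FALSE)
  s_lung <- mean(x[inl]); s_bg <- mean(x[bg])
  sigma_m <- stats::sd(x[bg])
  if (!is.finite(sigma_m) || sigma_m == 0)
    return(structure(list(s_lung = s_lung, s_bg = s_bg, sigma_m = sigma_m,
                          sigma_bg = NA_real_, snr = NA_real_,
                          n_background = sum(bg), variant = variant),
                     class = "snr_report"))
  sigma_bg <- sigma_m / sqrt(2 - pi / 2)
  snr <- if (variant == "bgsub") (s_lung - s_bg) / sigma_bg else s_lung / sigma_bg
  structure(list(s_lung = s_lung, s_bg = s_bg, sigma_m = sigma_m,
                 sigma_bg = sigma_bg, snr = snr, n_background = sum(bg),
                 variant = variant),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> SNR = %.2f (S_lung %.3g, sigma_bg %.3g, %s)\n",
              x$snr, x$s_lung, x$sigma_bg, x$variant))
  invisible(x)
}

#' Bias-field correction
#'
#' `"polynomial"` fits an order-2 3D polynomial to the log-intensity inside
#' the mask and divides the field out (mean signal preserved); `"external_n4"`
#' delegates to an N4 executable on the PATH when present, falling back to the
#' polynomial fit with a warning; `"none"` is the identity.
#'
#' @param vol magnitude [image_volume].
#' @param mask a [lung_mask].
#' @param method `"none"`, `"polynomial"` or `"external_n4"`.
#' @return list with `vol` (corrected) and `field` (multiplicative bias map,
#'   mean 1 inside the mask).
#' @export
bias_correct <- function(vol, mask, method = c("polynomial", "none",
                                               "external_n4")) {
  method <- match.arg(method)
  if (method == "none")
    return(list(vol = vol, field = array(1, dim(vol$data))))
  if (method == "external_n4") {
    if (nzchar(Sys.which("N4BiasFieldCorrection"))) {
      return(bias_correct_n4(vol, mask))
    }
    warning("external N4 tool not found; using polynomial fit", call. = FALSE)
  }
  x <- vol$data; d <- dim(x)
  inl <- mask_lung(mask) & x > 0
  u <- (slice.index(x, 1) - 1) / max(d[1] - 1, 1) - 0.5
  v <- (slice.index(x, 2) - 1) / max(d[2] - 1, 1) - 0.5
  w <- (slice.index(x, 3) - 1) / max(d[3] - 1, 1) - 0.5
  X <- cbind(1, u[inl], v[inl], w[inl], u[inl]^2, v[inl]^2, w[inl]^2,
             u[inl] * v[inl], u[inl] * w[inl], v[inl] * w[inl])
  beta <- stats::lm.fit(X, log(x[inl]))$coefficients
  beta[is.na(beta)] <- 0
  Xall <- cbind(1, c(u), c(v), c(w), c(u)^2, c(v)^2, c(w)^2,
                c(u) * c(v), c(u) * c(w), c(v) * c(w))
  field <- array(exp(Xall %*% beta), d)
  field <- field / mean(field[inl])
  out <- x / field
  list(vol = image_volume(out, vol$spacing, vol$plane, meta = vol$meta),
       field = field)
}

bias_correct_n4 <- function(vol, mask) {
  td <- tempfile("n4"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  inp <- file.path(td, "in.nii.gz"); outp <- file.path(td, "out.nii.gz")
  write_image_volume(vol, inp)
  status <- system2("N4BiasFieldCorrection",
                    c("-d", "3", "-i", inp, "-o", outp), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0 || !file.exists(outp)) {
    warning("external N4 run failed; using polynomial fit", call. = FALSE)
    return(bias_correct(vol, mask, "polynomial"))
  }
  corr <- read_image_volume(outp)$data
  field <- vol$data / pmax(corr, .Machine$double.eps)
  list(vol = image_volume(corr, vol$spacing, vol$plane, meta = vol$meta),
       field = field)
}

# slice-wise 3x3 binary median filter on the defect mask, mask-aware: the
# majority is taken over the in-lung voxels of each window only, so lung
# boundaries neither erode genuine defects nor import background votes
median3x3_slicewise <- function(defect3d, lung3d) {
  d <- dim(defect3d)
  k <- matrix(1, 3, 3)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    cntd <- EBImage::filter2(matrix(as.numeric(defect3d[, , z]), d[1], d[2]),
                             k, boundary = 0)
    cntl <- EBImage::filter2(matrix(as.numeric(lung3d[, , z]), d[1], d[2]),
                             k, boundary = 0)
    out[, , z] <- (2 * cntd > cntl + 1e-9) & lung3d[, , z]
  }
  out
}

#' Threshold VDP
#'
#' Classifies in-lung voxels below `frac` of the mean whole-lung signal as
#' defects, cleans the binary defect mask with a slice-wise 3x3 median filter
#' (removing isolated hot/cold voxels), and reports
#' `VDP = 100 (1 - VV/TLV)`, the defect percentage of lung volume.
#'
#' @param vol magnitude [image_volume].
#' @param mask a [lung_mask] (airways excluded).
#' @param frac threshold as a fraction of the whole-lung mean (default 0.60).
#' @return list with `vdp` (percent), `defect_mask` (logical array),
#'   `threshold`, `bin_map` (2-bin classification).
#' @export
vdp_threshold <- function(vol, mask, frac = 0.60) {
  x <- vol$data
  inl <- mask_lung(mask)
  if (!any(inl)) stop("empty lung mask")
  thr <- frac * mean(x[inl])
  defect <- inl & x < thr
  defect <- median3x3_slicewise(defect, inl)
  vdp <- 100 * sum(defect) / sum(inl)
  labels <- array(0L, dim(x))
  labels[inl] <- 2L; labels[defect] <- 1L
  bm <- structure(list(labels = labels, bin_edges = thr,
                       bin_names = c("defect", "ventilated"),
                       percentages = c(defect = vdp, ventilated = 100 - vdp)),
                  class = "bin_map")
  list(vdp = vdp, defect_mask = defect, threshold = thr, bin_map = bm)
}

#' Rescale by the whole-image 99th percentile
#'
#' Divides by the 99th percentile of the cumulative intensity distribution of
#' the whole image excluding airway voxels, then clips to \[0, 1\].
#'
#' @param vol magnitude [image_volume].
#' @param mask optional [lung_mask] supplying the airway label to exclude.
#' @return the normalized [image_volume] (attribute `scale` holds the divisor).
#' @export
rescale_99 <- function(vol, mask = NULL) {
  x <- vol$data
  excl <- if (!is.null(mask)) mask$labels == 2L else array(FALSE, dim(x))
  q <- stats::quantile(x[!excl], 0.99, names = FALSE)
  out <- pmin(pmax(x / q, 0), 1)
  v <- image_volume(array(out, dim(x)), vol$spacing, vol$plane, meta = vol$meta)
  attr(v, "scale") <- q
  v
}

#' Linear-binning VDP against a healthy reference
#'
#' Bins normalized in-lung intensities at the healthy-reference thresholds
#' mu-2s, mu-s, mu, mu+s, mu+2s into six classes: ventilation defect
#' (< mu-2s), low ventilation, two normal bins, two hyper-ventilation bins.
#' VDP is the defect-bin percentage; the low-ventilation percentage is
#' reported separately.
#'
#' @param norm_vol [image_volume] normalized to \[0, 1\] (see [rescale_99()]).
#' @param mask a [lung_mask].
#' @param ref a [healthy_reference]; the no-bias-correction 2D default is
#'   mu = 0.54, sigma = 0.15 and the bias-corrected default mu = 0.68,
#'   sigma = 0.14.
#' @return list with `vdp`, `low_percent`, `bin_map`.
#' @export
vdp_linear_binning <- function(norm_vol, mask,
                               ref = healthy_reference(0.68, 0.14)) {
  inl <- mask_lung(mask)
  if (!any(inl)) stop("empty lung mask")
  bm <- linear_bin_map(norm_vol$data, inl, ref$mu, ref$sigma)
  list(vdp = unname(bm$percentages["defect"]),
       low_percent = unname(bm$percentages["low"]),
       bin_map = bm)
}

# deterministic 1D k-means: percentile initialization + Lloyd iterations
kmeans_1d <- function(x, k = 4, restarts = 10) {
  qs <- (2 * seq_len(k) - 1) / (2 * k)
  centers <- stats::quantile(x, qs, names = FALSE)
  for (r in seq_len(restarts)) {
    if (length(unique(centers)) == k) {
      km <- tryCatch(stats::kmeans(x, centers = matrix(centers, ncol = 1),
                                   iter.max = 100, algorithm = "Lloyd"),
                     error = function(e) NULL)
      if (!is.null(km)) {
        ord <- order(km$centers)
        cl <- match(km$cluster, ord)
        return(list(cluster = cl, centers = sort(as.numeric(km$centers))))
      }
    }
    # deterministic re-seed: nudge towards the data quantile grid
    centers <- stats::quantile(x, (seq_len(k) - 0.5 + 0.1 * r) / (k + 0.2 * r),
                               names = FALSE)
  }
  stop("k-means failed to produce ", k, " nonempty clusters")
}

#' Hierarchical k-means VDP
#'
#' Three-step hierarchical clustering of in-lung intensities: (1) k-means
#' with four clusters on the image; (2) k-means with four clusters on the
#' lowest cluster C1 (signal void + hypointense); (3) the first two
#' sub-clusters of C1 become defect, the last two hypointense. VDP is the
#' defect percentage of lung volume.
#'
#' @param vol magnitude [image_volume].
#' @param mask a [lung_mask].
#' @param seed unused by the deterministic percentile initialization but kept
#'   for interface stability.
#' @return list with `vdp`, `bin_map` (4 classes: defect, hypointense,
#'   normal, hyperintense), `centers`.
#' @export
vdp_kmeans <- function(vol, mask, seed = 1) {
  x <- vol$data
  inl <- mask_lung(mask)
  v <- x[inl]
  if (length(unique(v)) < 8) stop("need >= 8 distinct intensities for k-means")
  km1 <- kmeans_1d(v, 4)
  c1 <- km1$cluster == 1
  km2 <- kmeans_1d(v[c1], 4)
  cls <- integer(length(v))
  cls[!c1] <- km1$cluster[!c1] + 1L          # C2,C3,C4 -> 3,4,5
  cls[c1] <- ifelse(km2$cluster <= 2, 1L, 2L) # defect, hypointense
  # collapse to 4 display classes: defect, hypo, normal (C2+C3), hyper (C4)
  cls4 <- c(1L, 2L, 3L, 3L, 4L)[cls]
  labels <- array(0L, dim(x))
  labels[inl] <- cls4
  vdp <- 100 * sum(cls4 == 1L) / length(v)
  pct <- 100 * tabulate(cls4, 4) / length(v)
  nm <- c("defect", "hypointense", "normal", "hyperintense")
  bm <- structure(list(labels = labels, bin_edges = km1$centers,
                       bin_names = nm,
                       percentages = stats::setNames(pct, nm)),
                  class = "bin_map")
  list(vdp = vdp, bin_map = bm,
       centers = list(image = km1$centers, c1 = km2$centers))
}

#' Defect distribution index
#'
#' For every defect voxel, DDI is 100 times the fraction of lung voxels
#' within a Chebyshev neighbourhood of `radius_vox` that are themselves
#' defect; the whole-lung DDI is the mean over defect voxels (0 when there
#' are none). High values mean concentrated defects, low values dispersed
#' ones. `mode = "2D"` restricts neighbourhoods to the slice.
#'
#' @param defect_mask logical array of defect voxels (subset of the lung).
#' @param mask a [lung_mask].
#' @param mode `"2D"` or `"3D"`.
#' @param radius_vox neighbourhood radius in voxels (>= 1).
#' @return list with `mean`, `sd`, `map` (per-voxel DDI, NA off-defect).
#' @export
compute_ddi <- function(defect_mask, mask, mode = c("2D", "3D"),
                        radius_vox = 3) {
  mode <- match.arg(mode)
  if (radius_vox < 1) stop("`radius_vox` must be >= 1")
  lung <- mask$labels == 1L
  if (any(defect_mask & !lung)) stop("defect mask must lie inside the lung")
  fr <- ddi_fractions(as.logical(defect_mask), as.logical(lung),
                      dim(lung), as.integer(radius_vox), mode == "2D")
  map <- array(fr, dim(lung))
  vals <- fr[!is.na(fr)]
  list(mean = if (length(vals)) mean(vals) else 0,
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       map = map)
}

#' Gray-level run-length texture features
#'
#' Quantizes the normalized in-mask intensities to `levels` gray levels,
#' builds run-length matrices along the in-slice directions 0/45/90/135
#' degrees (runs are truncated at the mask boundary), and computes the
#' standard features, averaged over directions: SRE, LRE, GLN, RLN, RP,
#' LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE.
#'
#' @param norm_vol [image_volume] normalized to \[0, 1\].
#' @param mask a [lung_mask].
#' @param levels number of gray levels (default 32).
#' @param directions subset of `c(0, 45, 90, 135)` degrees.
#' @return one-row data frame of direction-averaged features.
#' @export
glrlm_features <- function(norm_vol, mask, levels = 32,
                           directions = c(0, 45, 90, 135)) {
  x <- norm_vol$data
  inl <- mask_lung(mask)
  g <- array(0L, dim(x))
  g[inl] <- pmin(pmax(ceiling(x[inl] * levels), 1L), levels)
  if (!any(inl)) stop("empty mask")
  if (length(unique(g[inl])) < 2)
    warning("fewer than 2 gray levels inside mask; texture features are ",
            "degenerate", call. = FALSE)
  d <- dim(x)
  steps <- list(`0` = c(1, 0), `45` = c(1, -1), `90` = c(0, 1),
                `135` = c(-1, -1))
  feats <- NULL
  for (ang in directions) {
    st <- steps[[as.character(ang)]]
    counts <- new.env(parent = emptyenv())
    np <- 0
    for (z in seq_len(d[3])) {
      gz <- g[, , z]
      if (!any(gz > 0)) next
      np <- np + sum(gz > 0)
      runs <- glrlm_runs_2d(gz, st)
      for (r in seq_len(nrow(runs))) {
        key <- paste(runs[r, 1], runs[r, 2])
        counts[[key]] <- (counts[[key]] %||% 0) + runs[r, 3]
      }
    }
    keys <- ls(counts)
    gl <- as.integer(sub(" .*", "", keys))
    rl <- as.integer(sub(".* ", "", keys))
    p <- vapply(keys, function(k) counts[[k]], 0)
    nr <- sum(p)
    sg <- tapply(p, gl, sum); sr <- tapply(p, rl, sum)
    f <- c(SRE = sum(p / rl^2) / nr, LRE = sum(p * rl^2) / nr,
           GLN = sum(sg^2) / nr, RLN = sum(sr^2) / nr, RP = nr / np,
           LGRE = sum(p / gl^2) / nr, HGRE = sum(p * gl^2) / nr,
           SRLGE = sum(p / (gl^2 * rl^2)) / nr,
           SRHGE = sum(p * gl^2 / rl^2) / nr,
           LRLGE = sum(p * rl^2 / gl^2) / nr,
           LRHGE = sum(p * gl^2 * rl^2) / nr)
    feats <- rbind(feats, f)
  }
  as.data.frame(t(colMeans(feats)))
}

# enumerate runs of equal gray level along direction `st` in one quantized
# slice (0 = outside mask, breaks runs); returns matrix (level, length, count)
glrlm_runs_2d <- function(gz, st) {
  d <- dim(gz)
  runs <- list()
  # starting points: all cells whose predecessor along -st is outside/edge
  xi <- slice.index(gz, 1); yi <- slice.index(gz, 2)
  px <- xi - st[1]; py <- yi - st[2]
  inside <- function(ax, ay) ax >= 1 & ax <= d[1] & ay >= 1 & ay <= d[2]
  prev_in <- inside(px, py)
  prev_val <- matrix(0L, d[1], d[2])
  prev_val[prev_in] <- gz[cbind(px[prev_in], py[prev_in])]
  starts <- which(gz > 0 & (!prev_in | prev_val == 0 | prev_val != gz))
  for (s in starts) {
    ax <- xi[s]; ay <- yi[s]; lev <- gz[ax, ay]; len <- 0L
    while (inside(ax, ay)[1] && gz[ax, ay] == lev) {
      len <- len + 1L; ax <- ax + st[1]; ay <- ay + st[2]
      if (ax < 1 || ax > d[1] || ay < 1 || ay > d[2]) break
    }
    runs[[length(runs) + 1L]] <- c(lev, len)
  }
  if (!length(runs)) return(matrix(0L, 0, 3))
  m <- do.call(rbind, runs)
  ag <- stats::aggregate(rep(1L, nrow(m)), by = list(m[, 1], m[, 2]), FUN = sum)
  as.matrix(ag)
}

#' Run the full ventilation analysis
#'
#' Orchestrates SNR, optional bias correction, the three VDP algorithms,
#' DDI on the threshold defect mask, and GLRLM texture.
#'
#' @param vol magnitude [image_volume].
#' @param mask a [lung_mask] with airways labeled.
#' @param ref [healthy_reference] for linear binning.
#' @param methods subset of `c("threshold", "linbin", "kmeans")`.
#' @param bias one of `"none"`, `"polynomial"`, `"external_n4"`.
#' @param ddi_radius neighbourhood radius for DDI.
#' @param seed RNG seed recorded for reproducibility.
#' @return object of class `ventilation_result`.
#' @export
run_ventilation <- function(vol, mask, ref = healthy_reference(0.68, 0.14),
                            methods = c("threshold", "linbin", "kmeans"),
                            bias = "none", ddi_radius = 3, seed = 1) {
  snr <- compute_snr(vol, mask)
  bc <- bias_correct(vol, mask, bias)
  work <- bc$vol
  vdp <- list(); bins <- list()
  thr_res <- NULL
  if ("threshold" %in% methods) {
    thr_res <- vdp_threshold(work, mask)
    vdp$threshold <- thr_res$vdp; bins$threshold <- thr_res$bin_map
  }
  norm <- rescale_99(work, mask)
  if ("linbin" %in% methods) {
    lb <- vdp_linear_binning(norm, mask, ref)
    vdp$linbin <- lb$vdp; bins$linbin <- lb$bin_map
    low_percent <- lb$low_percent
  } else low_percent <- NULL
  if ("kmeans" %in% methods) {
    kmr <- vdp_kmeans(work, mask, seed)
    vdp$kmeans <- kmr$vdp; bins$kmeans <- kmr$bin_map
  }
  vols <- mask_volumes(mask)
  tlv <- vols[["tlv_ml"]]
  vv <- tlv * (1 - (vdp$threshold %||% 0) / 100)
  ddi2 <- ddi3 <- NULL
  if (!is.null(thr_res)) {
    ddi2 <- compute_ddi(thr_res$defect_mask, mask, "2D", ddi_radius)
    ddi3 <- compute_ddi(thr_res$defect_mask, mask, "3D", ddi_radius)
  }
  texture <- tryCatch(glrlm_features(norm, mask), error = function(e) NULL)
  structure(list(vdp_percent = vdp, low_percent = low_percent, vv_ml = vv,
                 tlv_ml = tlv, bins = bins,
                 ddi_2d = ddi2[c("mean", "sd")], ddi_3d = ddi3[c("mean", "sd")],
                 ddi_maps = list(`2d` = ddi2$map, `3d` = ddi3$map),
                 texture = texture, snr = snr, seed = seed),
            class = "ventilation_result")
}

#' @export
print.ventilation_result <- function(x, ...) {
  cat("<ventilation_result>\n")
  for (nm in names(x$vdp_percent))
    cat(sprintf("  VDP [%s]: %.2f %%\n", nm, x$vdp_percent[[nm]]))
  cat(sprintf("  TLV %.1f mL, VV %.1f mL, SNR %.1f\n", x$tlv_ml, x$vv_ml,
              x$snr$snr))
  if (!is.null(x$ddi_2d))
    cat(sprintf("  DDI 2D %.1f +/- %.1f, 3D %.1f +/- %.1f\n",
                x$ddi_2d$mean, x$ddi_2d$sd, x$ddi_3d$mean, x$ddi_3d$sd))
  invisible(x)
}
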