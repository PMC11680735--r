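# Diffusion analysis: ADC mapping, age-adjusted reference binning, and
# stretched-exponential / cylinder morphometry models.

#' Diffusion stack container
#'
#' @param data 4D array (x, y, slices, b).
#' @param bvalues ascending b-values in s/cm^2; the first must be 0.
#' @param diffusion_time_ms diffusion time Delta, ms.
#' @param spacing voxel spacing, mm.
#' @return object of class `diffusion_stack`.
#' @export
diffusion_stack <- function(data, bvalues, diffusion_time_ms = NA_real_,
                            spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 4) stop("`data` must be 4D (x, y, slices, b)")
  if (length(bvalues) != dim(data)[4])
    stop("length(bvalues) must match the 4th data dimension")
  if (length(bvalues) < 2) stop("need at least 2 b-values")
  if (is.unsorted(bvalues, strictly = TRUE) || bvalues[1] != 0)
    stop("bvalues must be strictly ascending with b[1] = 0")
  structure(list(data = data, bvalues = as.numeric(bvalues),
                 diffusion_time_ms = diffusion_time_ms,
                 spacing = as.numeric(spacing[1:3])),
            class = "diffusion_stack")
}

#' @export
print.diffusion_stack <- function(x, ...) {
  cat(sprintf("<diffusion_stack> %s, b = {%s} s/cm^2\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$bvalues, collapse = ", ")))
  invisible(x)
}

ADC_CEILING <- 0.14  # cm^2/s, free diffusion of xenon in air

#' Fit an ADC map
#'
#' Mono-exponential decay `S(b) = S0 exp(-b ADC)` fitted per voxel:
#' `"loglinear"` is the closed-form least-squares slope of ln S on b;
#' `"weighted"` is weighted least squares with weights S_i^2 (log-transform
#' noise weighting); `"bayesian"` is the posterior mean of ADC on a grid over
#' \[0, 0.14\] cm^2/s under a Gaussian likelihood with S0 profiled out.
#' Voxels with nonpositive signal anywhere in the fit, a b = 0 signal below
#' `2 * noise_floor`, or an out-of-range ADC are invalidated, not failed
#' globally.
#'
#' @param stack a [diffusion_stack].
#' @param mask a [lung_mask] (or logical array).
#' @param method `"loglinear"`, `"weighted"` or `"bayesian"`.
#' @param noise_floor background noise SD used for the b0 exclusion (0 = off).
#' @param grid_res Bayesian ADC grid resolution, cm^2/s.
#' @return object of class `adc_map`: `adc`, `s0`, `r2`, `valid_mask`,
#'   `fit_method`.
#' @export
fit_adc <- function(stack, mask, method = c("loglinear", "weighted", "bayesian"),
                    noise_floor = 0, grid_res = 5e-4) {
  method <- match.arg(method)
  b <- stack$bvalues
  nb <- length(b)
  inl <- if (inherits(mask, "lung_mask")) mask$labels == 1L else as.logical(mask)
  d3 <- dim(stack$data)[1:3]
  S <- matrix(stack$data, ncol = nb)[which(inl), , drop = FALSE]
  ok <- rowSums(S <= 0) == 0
  if (noise_floor > 0) ok <- ok & S[, 1] > 2 * noise_floor
  adc <- s0 <- r2 <- rep(NA_real_, nrow(S))
  L <- log(pmax(S, .Machine$double.xmin))
  if (method == "loglinear") {
    # closed-form least-squares slope: ADC = -(Nb sum(b lnS) - sum b sum lnS)
    #                                        / (Nb sum b^2 - (sum b)^2)
    sb <- sum(b); sb2 <- sum(b^2)
    sl <- L %*% b; ssum <- rowSums(L)
    adc <- -as.numeric(nb * sl - sb * ssum) / (nb * sb2 - sb^2)
    icpt <- (ssum + adc * sb) / nb
    s0 <- exp(icpt)
  } else if (method == "weighted") {
    W <- S^2
    sw <- rowSums(W); swb <- W %*% b; swb2 <- W %*% b^2
    swl <- rowSums(W * L); swbl <- rowSums(W * rep(b, each = nrow(W)) * L)
    den <- as.numeric(sw * swb2 - swb^2)
    adc <- -as.numeric(sw * swbl - as.numeric(swb) * swl) / den
    s0 <- exp((swl + adc * as.numeric(swb)) / sw)
  } else {
    grid <- seq(0, ADC_CEILING, by = grid_res)
    E <- exp(-outer(b, grid))                       # nb x G
    # profile S0: S0*(g) = (S . e_g) / (e_g . e_g); RSS = |S|^2 - (S.e)^2/(e.e)
    SE <- S %*% E                                   # nvox x G
    ee <- colSums(E^2)
    rss <- rowSums(S^2) - sweep(SE^2, 2, ee, "/")
    rss <- pmax(rss, 0)
    # per-voxel noise scale from the best fit
    s2 <- pmax(apply(rss, 1, min) / max(nb - 2, 1), 1e-20)
    logpost <- -rss / (2 * s2)
    logpost <- logpost - apply(logpost, 1, max)
    w <- exp(logpost)
    adc <- as.numeric((w %*% grid) / rowSums(w))
    gi <- max.col(-rss)
    s0 <- SE[cbind(seq_len(nrow(S)), gi)] / ee[gi]
  }
  pred <- matrix(s0, nrow(S), nb) * exp(-outer(adc, b))
  ssres <- rowSums((S - pred)^2)
  sstot <- rowSums((S - rowMeans(S))^2)
  r2 <- 1 - ssres / pmax(sstot, .Machine$double.xmin)
  inrange <- is.finite(adc) & adc >= 0 & adc <= ADC_CEILING
  valid <- ok & inrange
  to_map <- function(v, keep_invalid = FALSE) {
    m <- array(NA_real_, d3)
    m[which(inl)] <- ifelse(valid | keep_invalid, v, NA_real_)
    m
  }
  vm <- array(FALSE, d3)
  vm[which(inl)] <- valid
  structure(list(adc = to_map(adc), s0 = to_map(s0, TRUE), r2 = to_map(r2, TRUE),
                 valid_mask = vm, fit_method = method),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  v <- x$adc[x$valid_mask & !is.na(x$adc)]
  cat(sprintf("<adc_map> %s fit, %d valid voxels, mean ADC %.4f cm^2/s\n",
              x$fit_method, length(v), mean(v)))
  invisible(x)
}

#' Age-adjusted healthy ADC reference
#'
#' Evaluates the linear age models for the healthy-reference mean and SD of
#' ADC; the defaults are `mu = 0.0002 age + 0.029` and
#' `sigma = 5e-5 age + 0.0121` cm^2/s, and both are user-overridable.
#'
#' @param age_years subject age (>= 0).
#' @param model named list `(slope_mu, intercept_mu, slope_sigma,
#'   intercept_sigma)`.
#' @return a [healthy_reference] with `mu`, `sigma` in cm^2/s.
#' @export
adc_reference <- function(age_years,
                          model = list(slope_mu = 2e-4, intercept_mu = 0.029,
                                       slope_sigma = 5e-5,
                                       intercept_sigma = 0.0121)) {
  if (age_years < 0) stop("age must be >= 0")
  healthy_reference(model$slope_mu * age_years + model$intercept_mu,
                    model$slope_sigma * age_years + model$intercept_sigma,
                    age_model = model)
}

#' Linear binning of an ADC map
#'
#' Applies the six-bin structure used for ventilation (edges mu-2s, mu-s, mu,
#' mu+s, mu+2s) to valid ADC voxels; the high bins capture elevated ADC
#' (enlarged airspaces).
#'
#' @param adcmap an `adc_map` from [fit_adc()].
#' @param mask a [lung_mask].
#' @param ref a [healthy_reference], e.g. from [adc_reference()].
#' @return a `bin_map`.
#' @export
adc_linear_binning <- function(adcmap, mask, ref) {
  valid <- adcmap$valid_mask & !is.na(adcmap$adc)
  if (!any(valid)) stop("no valid ADC voxels to bin")
  vals <- adcmap$adc
  vals[!valid] <- NA_real_
  linear_bin_map(vals, valid, ref$mu, ref$sigma)
}

#' Stretched-exponential morphometry fit
#'
#' Per-voxel fit of `S(b) = S0 exp(-(b DDC)^alpha)` with the distributed
#' diffusion coefficient DDC (cm^2/s) and heterogeneity index alpha in
#' (0, 1]; alpha = 1 recovers the mono-exponential model. The mean diffusive
#' length scale uses the free-diffusion form `LmD = sqrt(2 DDC Delta)`
#' (flagged on the result: the published empirical length-scale mapping can
#' be substituted via `length_scale_fn`).
#'
#' @param stack a [diffusion_stack] with at least 3 b-values.
#' @param mask a [lung_mask].
#' @param length_scale_fn function(ddc_cm2s, delta_ms) -> micrometres.
#' @return list of maps `ddc`, `alpha`, `lmd_um`, `s0`, plus `valid_mask` and
#'   `length_scale` label.
#' @export
fit_sem <- function(stack, mask, length_scale_fn = NULL) {
  b <- stack$bvalues
  if (length(b) < 3) stop("stretched-exponential fit needs >= 3 b-values")
  inl <- if (inherits(mask, "lung_mask")) mask$labels == 1L else as.logical(mask)
  d3 <- dim(stack$data)[1:3]
  S <- matrix(stack$data, ncol = length(b))[which(inl), , drop = FALSE]
  ll <- fit_adc(stack, mask, "loglinear")
  adc0 <- ll$adc[which(inl)]
  n <- nrow(S)
  ddc <- alpha <- s0 <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (any(S[v, ] <= 0)) next
    a0 <- min(max(adc0[v], 1e-4), ADC_CEILING)
    fit <- tryCatch(minpack.lm::nlsLM(
      s ~ S0 * exp(-(b * D)^al),
      data = data.frame(s = S[v, ], b = b),
      start = list(S0 = S[v, 1], D = a0, al = 0.95),
      lower = c(0, 1e-6, 0.05), upper = c(Inf, ADC_CEILING, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    ddc[v] <- cf[["D"]]; alpha[v] <- cf[["al"]]; s0[v] <- cf[["S0"]]
  }
  lsfn <- length_scale_fn %||%
    function(ddc, delta_ms) sqrt(2 * ddc * delta_ms / 1000) * 1e4
  lmd <- lsfn(ddc, stack$diffusion_time_ms)
  to_map <- function(v) { m <- array(NA_real_, d3); m[which(inl)] <- v; m }
  vm <- array(FALSE, d3); vm[which(inl)] <- !is.na(ddc)
  list(ddc = to_map(ddc), alpha = to_map(alpha), lmd_um = to_map(lmd),
       s0 = to_map(s0), valid_mask = vm,
       length_scale = if (is.null(length_scale_fn)) "free-diffusion sqrt(2 D Delta)"
       else "user")
}

# orientation-averaged cylinder-model signal; the b*DAN -> 0 limit is the
# removable singularity sqrt(pi/(4x)) erf(sqrt(x)) -> 1 - x/3
cm_signal <- function(b, S0, DT, DAN) {
  x <- b * DAN
  f <- ifelse(x < 1e-8, 1 - x / 3,
              sqrt(pi / (4 * pmax(x, 1e-300))) * erf_(sqrt(pmax(x, 0))))
  S0 * exp(-b * DT) * f
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Cylinder-model morphometry fit
#'
#' Per-voxel fit of the orientation-averaged cylinder signal
#' `S(b) = S0 exp(-b DT) sqrt(pi/(4 b DAN)) erf(sqrt(b DAN))` with
#' longitudinal and transverse diffusivities DL >= DT and anisotropy
#' `DAN = DL - DT`; DAN -> 0 collapses smoothly to isotropic decay. Geometric
#' outputs (acinar duct radius, sleeve depth, mean linear intercept, S/V,
#' alveolar density) require the published empirical inversion coefficients
#' and ship disabled; a `geometry_fn(DL, DT, DAN)` hook accepts one.
#'
#' @param stack a [diffusion_stack] with at least 4 b-values.
#' @param mask a [lung_mask].
#' @param geometry_fn optional mapping from diffusivities to geometry.
#' @return list of maps `dl`, `dt`, `dan`, `s0`, `valid_mask`, and `geometry`
#'   (NULL unless `geometry_fn` given).
#' @export
fit_cm <- function(stack, mask, geometry_fn = NULL) {
  b <- stack$bvalues
  if (length(b) < 4) stop("cylinder-model fit needs >= 4 b-values")
  inl <- if (inherits(mask, "lung_mask")) mask$labels == 1L else as.logical(mask)
  d3 <- dim(stack$data)[1:3]
  S <- matrix(stack$data, ncol = length(b))[which(inl), , drop = FALSE]
  ll <- fit_adc(stack, mask, "loglinear")
  adc0 <- ll$adc[which(inl)]
  n <- nrow(S)
  dt <- dan <- s0 <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (any(S[v, ] <= 0)) next
    a0 <- min(max(adc0[v], 1e-4), ADC_CEILING)
    fit <- tryCatch(minpack.lm::nlsLM(
      s ~ cm_signal(b, S0, DT, DAN),
      data = data.frame(s = S[v, ], b = b),
      start = list(S0 = S[v, 1], DT = 0.6 * a0, DAN = a0),
      lower = c(0, 1e-6, 0), upper = c(Inf, ADC_CEILING, ADC_CEILING),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    dt[v] <- cf[["DT"]]; dan[v] <- cf[["DAN"]]; s0[v] <- cf[["S0"]]
  }
  to_map <- function(v) { m <- array(NA_real_, d3); m[which(inl)] <- v; m }
  geometry <- if (!is.null(geometry_fn)) geometry_fn(dt + dan, dt, dan)
  vm <- array(FALSE, d3); vm[which(inl)] <- !is.na(dt)
  list(dl = to_map(dt + dan), dt = to_map(dt), dan = to_map(dan),
       s0 = to_map(s0), valid_mask = vm, geometry = geometry)
}

#' Run the full diffusion analysis
#'
#' ADC fitting (selected methods), SNR on the b0 image, and age-adjusted
#' linear binning of the first method's map; morphometry models on request.
#'
#' @param stack a [diffusion_stack].
#' @param mask a [lung_mask].
#' @param age_years subject age for the reference model.
#' @param methods subset of `c("loglinear", "weighted", "bayesian")`.
#' @param morphometry subset of `c("sem", "cm")`.
#' @return object of class `diffusion_result`.
#' @export
run_diffusion <- function(stack, mask, age_years = 30,
                          methods = "loglinear", morphometry = character(0)) {
  b0vol <- image_volume(stack$data[, , , 1, drop = TRUE], stack$spacing)
  snr <- compute_snr(b0vol, mask)
  maps <- lapply(methods, function(m)
    fit_adc(stack, mask, m, noise_floor = snr$sigma_bg %||% 0))
  names(maps) <- methods
  ref <- adc_reference(age_years)
  bins <- adc_linear_binning(maps[[1]], mask, ref)
  mean_adc <- vapply(maps, function(m)
    mean(m$adc[m$valid_mask & !is.na(m$adc)]), 0)
  morpho <- list()
  if ("sem" %in% morphometry) morpho$sem <- fit_sem(stack, mask)
  if ("cm" %in% morphometry) morpho$cm <- fit_cm(stack, mask)
  structure(list(adc_maps = maps, mean_adc = mean_adc, reference = ref,
                 bins = bins, morphometry = morpho, snr = snr,
                 age_years = age_years),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("<diffusion_result>\n")
  for (nm in names(x$mean_adc))
    cat(sprintf("  mean ADC [%s]: %.4f cm^2/s\n", nm, x$mean_adc[[nm]]))
  cat(sprintf("  reference (age %.0f): mu %.4f, sigma %.4f cm^2/s\n",
              x$age_years, x$reference$mu, x$reference$sigma))
  print(x$bins)
  invisible(x)
}
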