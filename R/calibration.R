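# Calibration spectroscopy: flip-angle scale factor, gas frequency offset,
# dissolved-phase spectral fit, TE90, optimal flip angles.

wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' FID train to spectrum
#'
#' Averages FIDs over excitations, optionally applies exponential
#' (Lorentzian) apodization that adds `apodization_hz` to every linewidth,
#' and FFTs to a frequency axis centred on the transmitter.
#'
#' @param fids complex matrix (excitations x readout) or a single complex FID.
#' @param dwell_s dwell time, s.
#' @param apodization_hz exponential line broadening in Hz (0 = none).
#' @return list with `freq_hz`, `complex`, `magnitude`.
#' @export
fids_to_spectrum <- function(fids, dwell_s, apodization_hz = 0) {
  if (!is.matrix(fids)) fids <- matrix(fids, nrow = 1)
  if (nrow(fids) < 1 || all(Mod(fids) == 0)) stop("no nonzero FID data")
  avg <- colMeans(fids)
  np <- length(avg)
  t <- (seq_len(np) - 1) * dwell_s
  if (apodization_hz > 0) avg <- avg * exp(-pi * apodization_hz * t)
  spec <- stats::fft(avg) / sqrt(np)
  # reorder so the axis runs negative -> positive through 0 at the transmitter
  half <- ceiling(np / 2)
  ord <- c((half + 1):np, 1:half)
  freq <- ((seq_len(np) - 1) / np)
  freq <- ifelse(freq >= 0.5, freq - 1, freq) / dwell_s
  list(freq_hz = freq[ord], complex = spec[ord], magnitude = Mod(spec[ord]))
}

#' Fit the flip angle from an FID-train decay
#'
#' Each RF pulse consumes non-renewable hyperpolarized magnetization, so the
#' k-zero magnitude of excitation i follows `S_i = S0 * cos(alpha)^(i-1) + C`
#' (T1 relaxation neglected). The fit is nonlinear least squares over
#' (S0, alpha, C); `scale_factor = prescribed / fitted` rescales future
#' prescriptions.
#'
#' @param magnitudes per-excitation k-zero magnitudes (>= 3, nonnegative).
#' @param prescribed_flip_deg flip angle that was prescribed.
#' @return object of class `flip_decay_fit` with fields `S0`, `alpha_fit_deg`,
#'   `C`, `prescribed_flip_deg`, `scale_factor`, `residual_rms`, `failed`.
#' @export
fit_flip_angle <- function(magnitudes, prescribed_flip_deg) {
  if (length(magnitudes) < 3) stop("need at least 3 excitations")
  if (any(magnitudes < 0)) stop("magnitudes must be nonnegative")
  # long trains decay into the Rician noise floor, whose magnitude bias is
  # not captured by the additive offset C; drop the floor-dominated tail
  if (length(magnitudes) >= 30) {
    floor_est <- stats::median(utils::tail(magnitudes,
                                           max(5, length(magnitudes) %/% 10)))
    if (floor_est < 0.25 * max(magnitudes)) {
      sm <- stats::runmed(magnitudes, 5)
      above <- which(sm > 3 * floor_est)
      keep_n <- max(10, if (length(above)) max(above) else 0)
      magnitudes <- magnitudes[seq_len(min(keep_n, length(magnitudes)))]
    }
  }
  i <- seq_along(magnitudes)
  # log-linear start ignoring C
  pos <- magnitudes > 0
  sl <- stats::coef(stats::lm(log(magnitudes[pos]) ~ i[pos]))
  a0 <- acos(min(max(exp(sl[2]), 1e-6), 1 - 1e-9))
  fit <- tryCatch(minpack.lm::nlsLM(
    m ~ S0 * cos(a)^(i - 1) + C,
    data = data.frame(m = magnitudes, i = i),
    start = list(S0 = max(magnitudes), a = max(a0, 1e-3), C = 0),
    lower = c(0, 0.1 * pi / 180, -Inf), upper = c(Inf, 89.9 * pi / 180, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  failed <- FALSE
  if (is.null(fit)) {
    warning("flip-angle fit did not converge; series may be non-decaying",
            call. = FALSE)
    cf <- c(S0 = max(magnitudes), a = 0.1 * pi / 180, C = 0)
    failed <- TRUE
    resid_rms <- NA_real_
  } else {
    cf <- stats::coef(fit)
    resid_rms <- sqrt(mean(stats::resid(fit)^2))
    if (cf[["a"]] <= 0.1001 * pi / 180 || cf[["a"]] >= 89.89 * pi / 180) {
      warning("fitted flip angle hit its bounds; flagged as failed",
              call. = FALSE)
      failed <- TRUE
    }
  }
  alpha <- cf[["a"]] * 180 / pi
  structure(list(S0 = cf[["S0"]], alpha_fit_deg = alpha, C = cf[["C"]],
                 prescribed_flip_deg = prescribed_flip_deg,
                 scale_factor = prescribed_flip_deg / alpha,
                 residual_rms = resid_rms, failed = failed),
            class = "flip_decay_fit")
}

#' @export
print.flip_decay_fit <- function(x, ...) {
  cat(sprintf("<flip_decay_fit> alpha = %.3f deg (prescribed %.3f), scale %.4f%s\n",
              x$alpha_fit_deg, x$prescribed_flip_deg, x$scale_factor,
              if (x$failed) " [FAILED]" else ""))
  invisible(x)
}

lorentz_mag <- function(f, A, f0, w) A * (w / 2)^2 / ((f - f0)^2 + (w / 2)^2)

#' Fit the gas-phase frequency offset
#'
#' Fits a single Lorentzian line to the complex spectrum around the dominant
#' peak, using the exact finite-acquisition line shape (the geometric-sum DFT
#' of a decaying complex exponential), so the centre is resolved far below
#' the FFT bin width even for truncated FIDs. The offset is the fitted centre
#' relative to the transmitter (0 Hz).
#'
#' @param spectrum output of [fids_to_spectrum()].
#' @return list with `freq_offset_hz`, `fwhm_hz`, `ambiguous` flag.
#' @export
fit_gas_frequency <- function(spectrum) {
  mag <- spectrum$magnitude; f <- spectrum$freq_hz
  np <- length(f)
  dfreq <- f[2] - f[1]
  dwell <- 1 / (np * dfreq)
  sm <- stats::filter(mag, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  ipk <- which.max(sm)
  # secondary peak comparable to the primary -> ambiguous
  loc <- which(diff(sign(diff(sm))) == -2) + 1
  loc <- loc[order(sm[loc], decreasing = TRUE)]
  ambiguous <- length(loc) > 1 && sm[loc[2]] > 0.8 * sm[loc[1]]
  if (ambiguous)
    warning("two comparable spectral peaks; fitting the larger", call. = FALSE)
  if (ipk <= 2 || ipk >= np - 1)
    warning("dominant peak at spectral edge; possible aliasing", call. = FALSE)
  ipk <- which.max(mag * (abs(f - f[ipk]) < 3 * dfreq + 1e-9))
  win <- max(1, ipk - 15):min(np, ipk + 15)
  y <- c(Re(spectrum$complex[win]), Im(spectrum$complex[win]))
  line <- function(p) {
    z <- exp((2i * pi * (p[3] - f[win]) - pi * exp(p[4])) * dwell)
    s <- p[1] * exp(1i * p[2]) / sqrt(np) * (1 - z^np) / (1 - z)
    c(Re(s), Im(s))
  }
  p0 <- c(mag[ipk] * sqrt(np) * pi * 4 * dfreq * dwell, 0, f[ipk],
          log(4 * dfreq))
  fit <- minpack.lm::nls.lm(p0, fn = function(p) y - line(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  cf <- fit$par
  list(freq_offset_hz = cf[3], fwhm_hz = exp(cf[4]), ambiguous = ambiguous)
}

spectral_peak <- function(name, amplitude, freq_hz, fwhm_hz, phase_deg,
                          hz_per_ppm = NA_real_) {
  structure(list(name = name, amplitude = amplitude, freq_hz = freq_hz,
                 ppm = freq_hz / hz_per_ppm, fwhm_hz = fwhm_hz,
                 phase_deg = wrap_deg(phase_deg),
                 t2star_ms = 1000 / (pi * fwhm_hz)),
            class = "spectral_peak")
}

#' Fit the dissolved-phase spectrum
#'
#' Discards the initial `discard_first` dissolved FIDs (xenon still arriving
#' through large downstream vasculature during inhalation), averages the
#' rest, and fits a sum of three complex Lorentzians — RBC, membrane, gas —
#' in the time domain (amplitude, frequency, linewidth and phase each),
#' initialized from magnitude-spectrum peak picking. T2* per peak is
#' `1000/(pi * FWHM)` ms.
#'
#' @param fids complex matrix of dissolved FIDs (excitations x readout).
#' @param dwell_s dwell time, s.
#' @param te_ms echo time of the calibration scan, ms.
#' @param discard_first dissolved FIDs to discard (default 100).
#' @return list with `peaks` (named list of `spectral_peak`:
#'   rbc/membrane/gas), `rbc_membrane_ratio`, `n_averaged`, `residual_rms`,
#'   `contamination` (gas amplitude fraction of total dissolved signal).
#' @export
fit_dissolved_spectrum <- function(fids, dwell_s, te_ms = 0.45,
                                   discard_first = 100) {
  if (!is.matrix(fids)) fids <- matrix(fids, nrow = 1)
  if (nrow(fids) < discard_first + 10)
    stop("need at least discard_first + 10 = ", discard_first + 10, " FIDs")
  keep <- fids[(discard_first + 1):nrow(fids), , drop = FALSE]
  avg <- colMeans(keep)
  np <- length(avg)
  t <- (seq_len(np) - 1) * dwell_s
  # initialize from the three tallest well-separated peaks of a zero-padded
  # (finely resolved) magnitude spectrum
  pad <- c(avg, rep(0i, 7 * np))
  spec <- fids_to_spectrum(matrix(pad, nrow = 1), dwell_s)
  sm <- stats::filter(spec$magnitude, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  loc <- which(diff(sign(diff(sm))) == -2) + 1     # local maxima only
  loc <- loc[order(sm[loc], decreasing = TRUE)]
  cand <- numeric(0)
  for (i in loc) {
    if (length(cand) == 3) break
    if (all(abs(spec$freq_hz[i] - cand) > 300)) cand <- c(cand, spec$freq_hz[i])
  }
  cand <- sort(cand, decreasing = TRUE)      # rbc > membrane > gas frequency
  while (length(cand) < 3) cand <- c(cand, min(spec$freq_hz) / 2)
  y <- c(Re(avg), Im(avg))
  model <- function(p) {
    s <- lorentzian_fid(t, p[1], p[4], exp(p[7]), p[10] * 180 / pi) +
      lorentzian_fid(t, p[2], p[5], exp(p[8]), p[11] * 180 / pi) +
      lorentzian_fid(t, p[3], p[6], exp(p[9]), p[12] * 180 / pi)
    c(Re(s), Im(s))
  }
  a0 <- Mod(avg[1])
  p0 <- c(rep(a0 / 2, 3), cand, log(c(150, 150, 30)), rep(0, 3))
  fit <- minpack.lm::nls.lm(p0, fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  if (fit$info == 0 || any(!is.finite(fit$par)))
    stop("dissolved spectral fit did not converge; last residual RMS ",
         signif(sqrt(mean(fit$fvec^2)), 4))
  p <- fit$par
  # normalize amplitude sign into phase
  for (k in 1:3) if (p[k] < 0) { p[k] <- -p[k]; p[k + 9] <- p[k + 9] + pi }
  peaks <- list(
    rbc = spectral_peak("rbc", p[1], p[4], exp(p[7]), p[10] * 180 / pi),
    membrane = spectral_peak("membrane", p[2], p[5], exp(p[8]), p[11] * 180 / pi),
    gas = spectral_peak("gas", p[3], p[6], exp(p[9]), p[12] * 180 / pi))
  list(peaks = peaks,
       rbc_membrane_ratio = peaks$rbc$amplitude / peaks$membrane$amplitude,
       n_averaged = nrow(keep),
       residual_rms = sqrt(mean(fit$fvec^2)),
       contamination = peaks$gas$amplitude /
         (peaks$rbc$amplitude + peaks$membrane$amplitude + peaks$gas$amplitude))
}

#' Echo time for 90-degree RBC/membrane phase separation
#'
#' 1-point Dixon separation requires the RBC and membrane signals to be 90
#' degrees apart at k-zero. Given the phase separation already present at the
#' calibration echo time and the frequency difference between the peaks, the
#' required echo time is
#' `TE90 = TE + (90 - (phi_RBC - phi_mem)) / (360 * (f_RBC - f_mem))`,
#' with phases wrapped to (-180, 180] degrees and the increment converted
#' to ms.
#'
#' @param peaks named list with `rbc` and `membrane` `spectral_peak`s.
#' @param te_ms calibration echo time, ms.
#' @return TE90 in ms.
#' @export
compute_te90 <- function(peaks, te_ms) {
  if (is.null(peaks$rbc) || is.null(peaks$membrane))
    stop("rbc and membrane peaks required")
  df <- peaks$rbc$freq_hz - peaks$membrane$freq_hz
  if (abs(df) < 1) stop("degenerate peak separation (<1 Hz)")
  dphi <- wrap_deg(peaks$rbc$phase_deg - peaks$membrane$phase_deg)
  te_ms + 1000 * (90 - dphi) / (360 * df)
}

#' Optimal flip angle for an imaging sequence
#'
#' For ventilation and diffusion, maximizes the mean signal over the
#' excitation train as a function of flip angle. Cartesian encoding uses the
#' continuous-sum form `sin(a) (cos(a)^Neff - 1) / ln cos(a)` with
#' `Neff = N` (ventilation) or `N * Nb` (diffusion); center-out trajectories
#' use the discrete mean of the k-zero signals,
#' `sin(a) (1 - cos(a)^(N Nb)) / (N (1 - cos(a)^Nb))` (with `Nb = 1` for
#' ventilation). Gas exchange uses the fixed consortium pair: 0.5 degrees
#' (gas) and 20 degrees (dissolved).
#'
#' @param sequence `"ventilation"`, `"diffusion"` or `"gas_exchange"`.
#' @param trajectory `"cartesian"` or `"center_out"`.
#' @param N excitations per slice/volume.
#' @param Nb number of b-values (diffusion only).
#' @return optimal flip in degrees; for gas exchange, a named vector
#'   `c(gas = 0.5, dissolved = 20)`.
#' @export
optimal_flip <- function(sequence = c("ventilation", "diffusion", "gas_exchange"),
                         trajectory = c("cartesian", "center_out"), N = 1,
                         Nb = 1) {
  sequence <- match.arg(sequence)
  if (sequence == "gas_exchange") return(c(gas = 0.5, dissolved = 20))
  trajectory <- match.arg(trajectory)
  if (N < 1) stop("N must be >= 1")
  nb <- if (sequence == "diffusion") Nb else 1
  obj <- if (trajectory == "cartesian") {
    neff <- N * nb
    if (neff < 2) stop("Cartesian objective needs N >= 2")
    # continuous-sum mean-signal objective: sin(a) (cos^Neff(a) - 1) / ln cos(a)
    function(a) sin(a) * (cos(a)^neff - 1) / log(cos(a))
  } else {
    function(a) sin(a) * (1 - cos(a)^(N * nb)) / (N * (1 - cos(a)^nb))
  }
  if (trajectory == "center_out" && N * nb == 1) return(90)
  opt <- stats::optimize(obj, interval = c(1e-4, pi / 2 - 1e-6),
                         maximum = TRUE, tol = 1e-10)
  opt$maximum * 180 / pi
}

#' Run the full calibration analysis
#'
#' Splits an FID train into dissolved and gas blocks by ppm tag, then: fits
#' the gas k-zero decay for the flip angle and scale factor; fits the
#' averaged gas spectrum for the frequency offset; fits the dissolved
#' spectrum for the RBC/membrane/gas peaks, their T2*s and the RBC:membrane
#' ratio; computes TE90; and evaluates optimal flip angles. Sub-fit failures
#' are flagged on the result, never silently defaulted.
#'
#' @param raw a [raw_acquisition] of kind `fid_train` with gas/dissolved
#'   ppm tagging.
#' @param prescribed_flip_deg prescribed flip angle; defaults to the header.
#' @param discard_first dissolved FIDs discarded before averaging.
#' @param optimal_flip_specs named list of argument lists passed to
#'   [optimal_flip()].
#' @return object of class `calibration_result`.
#' @export
run_calibration <- function(raw, prescribed_flip_deg = raw$prescribed_flip_deg,
                            discard_first = 100,
                            optimal_flip_specs = list(
                              ventilation = list(sequence = "ventilation",
                                                 trajectory = "cartesian",
                                                 N = 128),
                              gas_exchange = list(sequence = "gas_exchange"))) {
  stopifnot(inherits(raw, "raw_acquisition"))
  if (raw$kind != "fid_train") stop("calibration needs a fid_train acquisition")
  is_gas <- raw$ppm_offset == 0
  failures <- character(0)
  flip_fit <- NULL; freq <- NULL
  if (!any(is_gas)) {
    failures <- c(failures, "flip_angle", "gas_frequency")
  } else {
    gas <- raw$samples[is_gas, , drop = FALSE]
    flip_fit <- tryCatch(fit_flip_angle(Mod(gas[, 1]), prescribed_flip_deg),
                         error = function(e) { failures <<- c(failures, "flip_angle"); NULL })
    freq <- tryCatch(fit_gas_frequency(fids_to_spectrum(gas, raw$dwell_s)),
                     error = function(e) { failures <<- c(failures, "gas_frequency"); NULL })
    if (!is.null(flip_fit) && isTRUE(flip_fit$failed))
      failures <- c(failures, "flip_angle")
  }
  dis_fit <- NULL; te90 <- NULL
  if (!any(!is_gas)) {
    failures <- c(failures, "dissolved_fit", "te90")
  } else {
    dis <- raw$samples[!is_gas, , drop = FALSE]
    dis_fit <- tryCatch(
      fit_dissolved_spectrum(dis, raw$dwell_s, raw$te_ms, discard_first),
      error = function(e) { failures <<- c(failures, "dissolved_fit"); NULL })
    te90 <- if (!is.null(dis_fit))
      tryCatch(compute_te90(dis_fit$peaks, raw$te_ms),
               error = function(e) { failures <<- c(failures, "te90"); NULL })
  }
  flips <- lapply(optimal_flip_specs, function(sp) do.call(optimal_flip, sp))
  structure(list(flip_fit = flip_fit,
                 freq_offset_hz = freq$freq_offset_hz,
                 peaks = dis_fit$peaks,
                 rbc_membrane_ratio = dis_fit$rbc_membrane_ratio,
                 contamination = dis_fit$contamination,
                 te_ms = raw$te_ms, te90_ms = te90, tr_ms = raw$tr_ms,
                 optimal_flips_deg = flips,
                 failures = unique(failures)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  if (!is.null(x$flip_fit))
    cat(sprintf("  flip: %.2f deg fitted / %.2f prescribed (scale %.4f)\n",
                x$flip_fit$alpha_fit_deg, x$flip_fit$prescribed_flip_deg,
                x$flip_fit$scale_factor))
  if (!is.null(x$freq_offset_hz))
    cat(sprintf("  gas frequency offset: %.2f Hz\n", x$freq_offset_hz))
  if (!is.null(x$rbc_membrane_ratio))
    cat(sprintf("  RBC:membrane = %.3f; TE90 = %.3f ms (TE %.3f, TR %.1f)\n",
                x$rbc_membrane_ratio, x$te90_ms %||% NA, x$te_ms, x$tr_ms))
  for (nm in names(x$optimal_flips_deg))
    cat(sprintf("  optimal flip [%s]: %s deg\n", nm,
                paste(round(x$optimal_flips_deg[[nm]], 2), collapse = "/")))
  if (length(x$failures))
    cat("  FAILED stages:", paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}
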