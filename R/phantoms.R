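# Synthetic phantoms: ground-truth inputs for every pipeline stage.
# Same (arguments, seed) always reproduces bit-identical output.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default dissolved-phase peak table
#'
#' Three Lorentzian resonances as seen from a transmitter centred on the
#' dissolved phase (218 ppm): RBC at 217 ppm, membrane at 198 ppm and gas at
#' 0 ppm, converted to Hz offsets at `hz_per_ppm`.
#'
#' @param hz_per_ppm scanner frequency in Hz per ppm (about 34.09 Hz/ppm for
#'   xenon-129 near 2.9 T).
#' @param rbc_mem_ratio RBC:membrane amplitude ratio of the scenario.
#' @return data frame with columns name, amp, freq_hz, fwhm_hz, phase_deg.
#' @export
default_dissolved_peaks <- function(hz_per_ppm = 34.09, rbc_mem_ratio = 0.53) {
  data.frame(
    name = c("rbc", "membrane", "gas"),
    amp = c(rbc_mem_ratio, 1, 0.15),
    freq_hz = (c(217, 198, 0) - 218) * hz_per_ppm,
    fwhm_hz = c(177, 159, 16),
    phase_deg = c(60, 15, 0))
}

lorentzian_fid <- function(t, amp, freq_hz, fwhm_hz, phase_deg) {
  amp * exp(1i * phase_deg * pi / 180) *
    exp((2i * pi * freq_hz - pi * fwhm_hz) * t)
}

#' Calibration FID-train phantom
#'
#' Simulates the dedicated calibration scan: `n_dissolved` FIDs excited at the
#' dissolved-phase frequency followed by `n_gas` FIDs at the gas frequency.
#' Gas excitation j is scaled by cos(flip)^(j-1) — the depletion of
#' non-renewable hyperpolarized magnetization by each RF pulse, the signal
#' model the flip-angle fit inverts. Dissolved magnetization is replenished
#' from the alveolar gas reservoir between excitations, so the dissolved
#' block holds a steady amplitude after an initial downstream-vasculature
#' transient decaying over `transient_tau` excitations (the reason the first
#' 100 dissolved FIDs are discarded). Each FID is a sum of complex
#' Lorentzians sampled at `dwell_s`; complex Gaussian noise of SD
#' `noise_sigma` per component is added.
#'
#' @param true_flip_deg applied flip angle (0, 90) degrees.
#' @param peaks dissolved peak table as from [default_dissolved_peaks()].
#' @param n_dissolved,n_gas excitation counts (defaults 500 and 20).
#' @param n_points readout points per FID.
#' @param dwell_s dwell time, s.
#' @param te_ms,tr_ms echo/repetition time recorded in the header (ms).
#' @param gas_freq_offset_hz true gas-phase frequency offset from the gas
#'   transmitter, Hz.
#' @param gas_fwhm_hz gas-peak linewidth, Hz.
#' @param noise_sigma complex noise SD (>= 0).
#' @param transient_amp,transient_tau relative amplitude and decay constant
#'   (in excitations) of the early dissolved-signal transient.
#' @param prescribed_flip_deg flip angle recorded as prescribed.
#' @param seed RNG seed.
#' @return list with `raw` (a [raw_acquisition], kind `fid_train`) and `truth`
#'   (the generating parameters).
#' @export
make_calibration_fids <- function(true_flip_deg, peaks = default_dissolved_peaks(),
                                  n_dissolved = 500, n_gas = 20, n_points = 256,
                                  dwell_s = 2e-5, te_ms = 0.45, tr_ms = 15,
                                  gas_freq_offset_hz = 0, gas_fwhm_hz = 16,
                                  noise_sigma = 0, transient_amp = 0.5,
                                  transient_tau = 25,
                                  prescribed_flip_deg = true_flip_deg, seed = 1) {
  if (true_flip_deg <= 0 || true_flip_deg >= 90)
    stop("`true_flip_deg` must be in (0, 90)")
  if (nrow(peaks) < 1) stop("`peaks` must be nonempty")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  t <- (seq_len(n_points) - 1) * dwell_s
  dis1 <- Reduce(`+`, lapply(seq_len(nrow(peaks)), function(k)
    lorentzian_fid(t, peaks$amp[k], peaks$freq_hz[k], peaks$fwhm_hz[k],
                   peaks$phase_deg[k])))
  gas1 <- lorentzian_fid(t, 1, gas_freq_offset_hz, gas_fwhm_hz, 0)
  ca <- cos(true_flip_deg * pi / 180)
  n <- n_dissolved + n_gas
  samples <- matrix(0i, n, n_points)
  for (i in seq_len(n_dissolved))
    samples[i, ] <- (1 + transient_amp * exp(-(i - 1) / transient_tau)) * dis1
  for (j in seq_len(n_gas)) samples[n_dissolved + j, ] <- ca^(j - 1) * gas1
  if (noise_sigma > 0)
    samples <- samples + with_seed(seed, matrix(complex(
      real = stats::rnorm(n * n_points, sd = noise_sigma),
      imaginary = stats::rnorm(n * n_points, sd = noise_sigma)), n, n_points))
  raw <- raw_acquisition("fid_train", samples, dwell_s = dwell_s,
                         tr_ms = tr_ms, te_ms = te_ms,
                         prescribed_flip_deg = prescribed_flip_deg,
                         ppm_offset = c(rep(218, n_dissolved), rep(0, n_gas)))
  list(raw = raw,
       truth = list(true_flip_deg = true_flip_deg, peaks = peaks,
                    gas_freq_offset_hz = gas_freq_offset_hz,
                    gas_fwhm_hz = gas_fwhm_hz, noise_sigma = noise_sigma,
                    seed = seed))
}

# two-ellipsoid lung geometry with a mediastinal gap and optional trachea;
# returns integer labels 0 background / 1 lung / 2 airway
lung_geometry <- function(shape, trachea = TRUE) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x <- slice.index(array(0, shape), 1)
  y <- slice.index(array(0, shape), 2)
  z <- slice.index(array(0, shape), 3)
  ell <- function(cx, cy, cz, rx, ry, rz)
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 + ((z - cz) / rz)^2 <= 1
  lung <- ell(0.30 * nx, 0.55 * ny, 0.5 * nz + 0.5,
              0.17 * nx, 0.36 * ny, 0.40 * nz) |
    ell(0.70 * nx, 0.55 * ny, 0.5 * nz + 0.5,
        0.17 * nx, 0.36 * ny, 0.40 * nz)
  labels <- array(0L, shape)
  labels[lung] <- 1L
  if (trachea) {
    tr <- (x - 0.5 * nx)^2 + (z - 0.5 * nz - 0.5)^2 <= (0.045 * nx)^2 &
      y >= 0.08 * ny & y <= 0.42 * ny
    labels[tr] <- 2L
  }
  labels
}

#' Ventilation phantom
#'
#' Two ellipsoidal lungs (signal 1.0) with a tracheal tube, spherical defects
#' at a reduced intensity fraction, an optional smooth multiplicative bias
#' field, and complex Gaussian noise scaled to reach a target SNR on the
#' magnitude image (so the background is Rayleigh-distributed, as assumed by
#' the SNR noise correction).
#'
#' @param shape volume dimensions, default `c(64, 64, 12)`.
#' @param defect_spec list of `list(center = c(x, y, z), radius, intensity_frac)`
#'   with `intensity_frac` in \[0, 1); centers must lie inside the lungs.
#' @param bias_spec `NULL` for no bias, or `list(amplitude =)` for a quadratic
#'   multiplicative field of that relative amplitude.
#' @param snr_target target SNR (`Inf` = noiseless).
#' @param spacing voxel spacing mm.
#' @param trachea include the airway tube.
#' @param seed RNG seed.
#' @return list with `vol` (magnitude [image_volume]), `mask` (a [lung_mask])
#'   and `truth` (defect count and voxel index set, bias field, noise sigma).
#' @export
make_ventilation_phantom <- function(shape = c(64, 64, 12), defect_spec = list(),
                                     bias_spec = NULL, snr_target = Inf,
                                     spacing = c(3, 3, 15), trachea = TRUE,
                                     seed = 1) {
  labels <- lung_geometry(shape, trachea)
  signal <- array(0, shape)
  signal[labels == 1L] <- 1
  signal[labels == 2L] <- 1.6  # free gas column, brighter than parenchyma
  defect_idx <- integer(0)
  x <- slice.index(signal, 1); y <- slice.index(signal, 2)
  z <- slice.index(signal, 3)
  for (d in defect_spec) {
    stopifnot(d$intensity_frac >= 0, d$intensity_frac < 1)
    ci <- round(d$center)
    if (labels[ci[1], ci[2], ci[3]] != 1L)
      stop("defect centre at (", paste(ci, collapse = ","),
           ") is outside the lungs")
    sph <- which((x - d$center[1])^2 + (y - d$center[2])^2 +
                   (z - d$center[3])^2 <= d$radius^2 & labels == 1L)
    signal[sph] <- d$intensity_frac
    defect_idx <- union(defect_idx, sph)
  }
  bias <- array(1, shape)
  if (!is.null(bias_spec)) {
    a <- bias_spec$amplitude %||% 0.3
    u <- (x / shape[1] - 0.5); v <- (y / shape[2] - 0.5)
    bias <- 1 + a * (u^2 + v^2 - u * v - mean(u^2 + v^2 - u * v))
  }
  clean <- signal * bias
  sigma <- 0
  if (is.finite(snr_target)) {
    # background sd of the Rayleigh magnitude is sigma*sqrt(2 - pi/2); the
    # corrected sigma_bg therefore equals the per-component complex sigma
    sigma <- mean(clean[labels == 1L]) / snr_target
    noisy <- with_seed(seed, Mod(complex(
      real = clean + stats::rnorm(length(clean), sd = sigma),
      imaginary = stats::rnorm(length(clean), sd = sigma))))
    mag <- array(noisy, shape)
  } else mag <- clean
  list(vol = image_volume(mag, spacing = spacing,
                          meta = list(phantom = "ventilation", seed = seed)),
       mask = lung_mask(labels, spacing),
       truth = list(defect_count = length(defect_idx),
                    defect_idx = defect_idx, labels = labels,
                    bias_field = bias, noise_sigma = sigma, seed = seed))
}

#' Multi-b diffusion phantom
#'
#' Signal decays with b-value as `S0 * exp(-b * ADC)` (mono-exponential) or
#' `S0 * exp(-(b * DDC)^alpha)` (stretched exponential) from a known per-lung
#' ground truth; complex Gaussian noise is added per b-image.
#'
#' @param adc_truth ADC (or DDC) in cm^2/s: one value, or two values used for
#'   the left and right lung.
#' @param bvalues ascending b-values in s/cm^2, first must be 0.
#' @param model `"mono"` or `"sem"`.
#' @param sem_alpha heterogeneity index in (0, 1], used when `model = "sem"`.
#' @param snr_target SNR at b = 0 (`Inf` = noiseless).
#' @param shape,spacing geometry.
#' @param diffusion_time_ms diffusion time recorded on the stack, ms.
#' @param seed RNG seed.
#' @return list with `stack` (a [diffusion_stack]), `mask` and `truth`.
#' @export
make_diffusion_phantom <- function(adc_truth = 0.03,
                                   bvalues = c(0, 7.5, 15, 22.5, 30),
                                   model = c("mono", "sem"), sem_alpha = 1,
                                   snr_target = Inf, shape = c(48, 48, 8),
                                   spacing = c(4, 4, 15),
                                   diffusion_time_ms = 5, seed = 1) {
  model <- match.arg(model)
  if (is.unsorted(bvalues, strictly = TRUE) || bvalues[1] != 0)
    stop("`bvalues` must be strictly ascending with b[1] = 0")
  if (sem_alpha <= 0 || sem_alpha > 1) stop("`sem_alpha` must be in (0, 1]")
  labels <- lung_geometry(shape, trachea = FALSE)
  nx <- shape[1]
  adc_map <- array(0, shape)
  if (length(adc_truth) == 1) adc_map[labels == 1L] <- adc_truth
  else {
    xi <- slice.index(adc_map, 1)
    adc_map[labels == 1L & xi <= nx / 2] <- adc_truth[1]
    adc_map[labels == 1L & xi > nx / 2] <- adc_truth[2]
  }
  nb <- length(bvalues)
  data <- array(0, c(shape, nb))
  for (i in seq_len(nb)) {
    dec <- if (model == "mono") exp(-bvalues[i] * adc_map)
    else exp(-(bvalues[i] * adc_map)^sem_alpha)
    data[, , , i] <- (labels == 1L) * dec
  }
  sigma <- 0
  if (is.finite(snr_target)) {
    sigma <- mean(data[, , , 1][labels == 1L]) / snr_target
    data <- with_seed(seed, {
      n <- length(data)
      array(Mod(complex(real = data + stats::rnorm(n, sd = sigma),
                        imaginary = stats::rnorm(n, sd = sigma))), dim(data))
    })
  }
  list(stack = diffusion_stack(data, bvalues, diffusion_time_ms, spacing),
       mask = lung_mask(labels, spacing),
       truth = list(adc_map = adc_map, model = model, sem_alpha = sem_alpha,
                    noise_sigma = sigma, seed = seed))
}

#' Gas-exchange phantom
#'
#' Composes complex gas and dissolved-phase volumes from known RBC, membrane
#' and gas maps. The dissolved image encodes RBC at 0 phase on the real axis
#' and membrane at 90 degrees on the imaginary axis, each attenuated by its
#' T2* at the echo time; both volumes carry a common B0 phase map, and complex
#' Gaussian noise is added.
#'
#' @param rbc_map,mem_map,gas_map nonnegative co-registered 3D arrays; when
#'   `NULL`, defaults are built on `shape`: gas 1.0 in the lungs, membrane
#'   with a smooth spatial modulation, RBC = `rbc_mem_ratio` x membrane.
#' @param b0_phase_map_deg B0 phase map in degrees (scalar or array).
#' @param t2stars_ms named or positional T2* for (gas, membrane, rbc), ms.
#' @param te90_ms echo time of the dissolved acquisition, ms (> 0).
#' @param flips_deg applied (gas, dissolved) flip angles, degrees.
#' @param rbc_mem_ratio scenario RBC:membrane ratio for the default maps.
#' @param noise_sigma complex noise SD.
#' @param shape,spacing geometry for default maps.
#' @param seed RNG seed.
#' @return list with complex `gas` and `dissolved` [image_volume]s, `mask`,
#'   and `truth` holding the generating maps, decay factors and the flip
#'   scale factor sin(dissolved)/sin(gas).
#' @export
make_gasexchange_phantom <- function(rbc_map = NULL, mem_map = NULL,
                                     gas_map = NULL, b0_phase_map_deg = 0,
                                     t2stars_ms = c(gas = 1.8, membrane = 2.0,
                                                    rbc = 1.8),
                                     te90_ms = 0.45,
                                     flips_deg = c(gas = 0.5, dissolved = 20),
                                     rbc_mem_ratio = 0.53, noise_sigma = 0,
                                     shape = c(32, 32, 32), spacing = c(6, 6, 6),
                                     seed = 1) {
  if (te90_ms <= 0) stop("`te90_ms` must be > 0")
  labels <- lung_geometry(shape, trachea = FALSE)
  if (is.null(gas_map)) gas_map <- (labels == 1L) * 1.0
  shape <- dim(gas_map)
  if (is.null(mem_map)) {
    y <- slice.index(array(0, shape), 2)
    mem_map <- (labels == 1L) * (1 + 0.2 * sin(2 * pi * y / shape[2]))
  }
  if (is.null(rbc_map)) rbc_map <- rbc_mem_ratio * mem_map
  if (any(rbc_map < 0) || any(mem_map < 0) || any(gas_map < 0))
    stop("maps must be nonnegative")
  b0 <- array(b0_phase_map_deg * pi / 180, shape)
  d <- exp(-te90_ms / t2stars_ms)
  dis <- (rbc_map * d[["rbc"]] + 1i * mem_map * d[["membrane"]]) * exp(1i * b0)
  gas <- gas_map * d[["gas"]] * exp(1i * b0)
  if (noise_sigma > 0) {
    add_noise <- function(x, off) with_seed(seed + off, x + complex(
      real = stats::rnorm(length(x), sd = noise_sigma),
      imaginary = stats::rnorm(length(x), sd = noise_sigma)))
    dis <- array(add_noise(dis, 0L), shape)
    gas <- array(add_noise(gas, 1L), shape)
  }
  flip_scale <- sin(flips_deg[["dissolved"]] * pi / 180) /
    sin(flips_deg[["gas"]] * pi / 180)
  list(gas = image_volume(gas, spacing = spacing,
                          meta = list(phantom = "gasexchange", channel = "gas")),
       dissolved = image_volume(dis, spacing = spacing,
                                meta = list(phantom = "gasexchange",
                                            channel = "dissolved")),
       mask = lung_mask(labels, spacing),
       truth = list(rbc_map = rbc_map, mem_map = mem_map, gas_map = gas_map,
                    b0_phase_deg = b0_phase_map_deg, t2stars_ms = t2stars_ms,
                    te90_ms = te90_ms, flips_deg = flips_deg,
                    decay = d, flip_scale = flip_scale,
                    rbc_mem_ratio = sum(rbc_map) / sum(mem_map),
                    noise_sigma = noise_sigma, seed = seed))
}

#' Forward-project complex volumes to interleaved 3D radial k-space
#'
#' Samples the discrete Fourier transform of the gas and dissolved volumes
#' along center-out radial spokes (spherical-Fibonacci directions), writing
#' gas and dissolved excitations interleaved, tagged by ppm offset — the raw
#' format the gas-exchange reconstruction consumes.
#'
#' @param gas_vol,dissolved_vol complex [image_volume]s of identical cubic shape.
#' @param n_spokes spokes per channel.
#' @param n_samples readout points per spoke.
#' @param dwell_s dwell time recorded in the header.
#' @param te90_ms echo time recorded in the header.
#' @return a [raw_acquisition] of kind `radial3d`.
#' @export
make_radial_raw <- function(gas_vol, dissolved_vol, n_spokes = 600,
                            n_samples = NULL, dwell_s = 1e-5, te90_ms = 0.45) {
  n <- dim(gas_vol$data)[1]
  stopifnot(all(dim(gas_vol$data) == n), all(dim(dissolved_vol$data) == dim(gas_vol$data)))
  if (is.null(n_samples)) n_samples <- n
  # spherical Fibonacci directions
  i <- seq_len(n_spokes) - 0.5
  phi <- acos(1 - 2 * i / n_spokes)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- rbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  r <- seq(0, 0.5, length.out = n_samples)
  traj1 <- array(0, c(3, n_samples, n_spokes))
  for (s in seq_len(n_spokes)) traj1[, , s] <- outer(dirs[, s], r)
  kflat <- matrix(traj1, nrow = 3)
  sg <- nudft3_forward(gas_vol$data, kflat)
  sd_ <- nudft3_forward(dissolved_vol$data, kflat)
  samples <- matrix(0i, 2 * n_spokes, n_samples)
  traj <- array(0, c(3, n_samples, 2 * n_spokes))
  ppm <- numeric(2 * n_spokes)
  for (s in seq_len(n_spokes)) {
    idx <- (s - 1) * n_samples + seq_len(n_samples)
    samples[2 * s - 1, ] <- sg[idx]
    samples[2 * s, ] <- sd_[idx]
    traj[, , 2 * s - 1] <- traj1[, , s]
    traj[, , 2 * s] <- traj1[, , s]
    ppm[2 * s - 1] <- 0; ppm[2 * s] <- 218
  }
  raw_acquisition("radial3d", samples, trajectory = traj, dwell_s = dwell_s,
                  te_ms = te90_ms, ppm_offset = ppm)
}
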