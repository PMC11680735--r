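test_that("spectra place tones at the right frequency and conserve energy", {
  dwell <- 2e-5
  t <- (0:255) * dwell
  tone <- matrix(exp(2i * pi * 100 * t), nrow = 1)
  sp <- fids_to_spectrum(tone, dwell)
  bin <- abs(sp$freq_hz[2] - sp$freq_hz[1])
  expect_lt(abs(sp$freq_hz[which.max(sp$magnitude)] - 100), bin + 1e-9)
  # Parseval with no apodization (unitary scaling)
  expect_equal(sum(Mod(tone)^2), sum(sp$magnitude^2), tolerance = 1e-6)
  expect_error(fids_to_spectrum(matrix(0i, 1, 8), dwell), "nonzero")
})

test_that("exponential apodization broadens a Lorentzian additively", {
  peaks <- data.frame(name = "x", amp = 1, freq_hz = 0, fwhm_hz = 20,
                      phase_deg = 0)
  ph <- make_calibration_fids(10, peaks = peaks, n_dissolved = 1, n_gas = 1,
                              n_points = 16384, dwell_s = 1e-4,
                              noise_sigma = 0)
  fid <- ph$raw$samples[1, , drop = FALSE]
  sp <- fids_to_spectrum(fid, 1e-4, apodization_hz = 10)
  expect_equal(measure_fwhm(sp$freq_hz, pmax(Re(sp$complex), 0)), 30,
               tolerance = 0.01)
})

test_that("flip-angle fit recovers a noiseless cosine-decay series exactly", {
  s <- 100 * cos(15 * pi / 180)^(0:19)
  fit <- fit_flip_angle(s, prescribed_flip_deg = 15)
  expect_equal(fit$alpha_fit_deg, 15, tolerance = 0.01)
  expect_lt(abs(fit$C), 1e-6)
  expect_equal(fit$S0, 100, tolerance = 1e-4)
  fit2 <- fit_flip_angle(s, prescribed_flip_deg = 20)
  expect_equal(fit2$scale_factor, 20 / 15, tolerance = 1e-3)
  expect_warning(fit_flip_angle(rep(5, 20), 10), "non-decaying|bounds")
  expect_error(fit_flip_angle(c(1, 2), 10), "at least 3")
})

test_that("Monte-Carlo flip recovery is unbiased within 1% at SNR 100", {
  est <- vapply(1:100, function(s) {
    m <- cos(20 * pi / 180)^(0:19)
    set.seed(s)
    mm <- Mod(complex(real = m + rnorm(20, sd = 0.01),
                      imaginary = rnorm(20, sd = 0.01)))
    fit_flip_angle(mm, 20)$alpha_fit_deg
  }, 0)
  expect_lt(abs(mean(est) - 20) / 20, 0.01)
})

test_that("gas frequency fit resolves offsets below the FFT bin width", {
  mk <- function(off) make_calibration_fids(
    10, n_dissolved = 1, n_gas = 10, gas_freq_offset_hz = off,
    noise_sigma = 0)
  for (off in c(62, 0)) {
    ph <- mk(off)
    gas <- ph$raw$samples[ph$raw$ppm_offset == 0, , drop = FALSE]
    r <- fit_gas_frequency(fids_to_spectrum(gas, 2e-5))
    expect_lt(abs(r$freq_offset_hz - off), 0.5)
  }
  # two comparable peaks are flagged ambiguous and the larger one fitted
  dwell <- 2e-5
  t <- (0:511) * dwell
  two <- matrix(1.2 * exp((2i * pi * 800 - pi * 30) * t) +
                  exp((-2i * pi * 3000 - pi * 30) * t), nrow = 1)
  expect_warning(r2 <- fit_gas_frequency(fids_to_spectrum(two, dwell)),
                 "comparable")
  expect_true(r2$ambiguous)
  expect_lt(abs(r2$freq_offset_hz - 800), 30)
})

test_that("dissolved-spectrum fit recovers amplitudes, widths and the ratio", {
  peaks <- default_dissolved_peaks()
  peaks$amp <- c(2, 4, 1)           # rbc, membrane, gas
  peaks$fwhm_hz[1] <- 31.83
  ph <- make_calibration_fids(20, peaks = peaks, noise_sigma = 0)
  dis <- ph$raw$samples[ph$raw$ppm_offset != 0, , drop = FALSE]
  r <- fit_dissolved_spectrum(dis, 2e-5)
  expect_equal(r$rbc_membrane_ratio, 0.5, tolerance = 0.02)
  expect_equal(r$n_averaged, 400)
  # T2* = 1000 / (pi FWHM): 31.83 Hz -> 10.0 ms
  expect_equal(r$peaks$rbc$t2star_ms, 10, tolerance = 0.1)
  expect_error(fit_dissolved_spectrum(dis[1:50, ], 2e-5), "at least")
})

test_that("T2* and linewidth satisfy their exact reciprocal relation", {
  ph <- make_calibration_fids(20, noise_sigma = 0)
  r <- fit_dissolved_spectrum(ph$raw$samples[ph$raw$ppm_offset != 0, ], 2e-5)
  for (p in r$peaks)
    expect_equal(p$t2star_ms * pi * p$fwhm_hz, 1000, tolerance = 1e-9)
})

test_that("TE90 follows the phase/frequency relation", {
  pk <- function(phi_rbc, phi_mem, f_rbc, f_mem) list(
    rbc = list(phase_deg = phi_rbc, freq_hz = f_rbc),
    membrane = list(phase_deg = phi_mem, freq_hz = f_mem))
  # 90-degree separation already achieved: TE90 = TE
  expect_equal(compute_te90(pk(90, 0, 300, -300), 0.45), 0.45)
  # hand-computed: TE 0.45 ms, dphi 0, df 647.7 Hz
  expect_equal(compute_te90(pk(0, 0, 0, -647.7), 0.45),
               0.45 + 1000 * 90 / (360 * 647.7), tolerance = 1e-9)
  expect_equal(compute_te90(pk(0, 0, 0, -647.7), 0.45), 0.836,
               tolerance = 5e-4)
  # 180-degree separation: negative increment, TE90 < TE
  expect_lt(compute_te90(pk(180, 0, 300, -300), 0.45), 0.45)
  # two further hand-computed combinations
  expect_equal(compute_te90(pk(45, -15, 200, -400), 0.50),
               0.50 + 1000 * (90 - 60) / (360 * 600), tolerance = 1e-9)
  expect_equal(compute_te90(pk(-170, 150, 100, -500), 0.40),
               0.40 + 1000 * (90 - 40) / (360 * 600), tolerance = 1e-9)
  # invariance under 360-degree phase wraps
  expect_equal(compute_te90(pk(30 + 360, 10, 300, -300), 0.45),
               compute_te90(pk(30, 10, 300, -300), 0.45))
  expect_error(compute_te90(pk(0, 0, 100, 100.5), 0.45), "degenerate")
})

test_that("optimal flip angles match the dense grid-search oracle", {
  expect_identical(optimal_flip("gas_exchange"), c(gas = 0.5, dissolved = 20))
  expect_equal(optimal_flip("ventilation", "center_out", N = 1), 90)
  for (N in c(16, 64, 128))
    expect_equal(optimal_flip("ventilation", "center_out", N = N),
                 oracle_centerout_flip(N), tolerance = 0.01)
  expect_equal(optimal_flip("diffusion", "center_out", N = 32, Nb = 4),
               oracle_centerout_flip(32, 4), tolerance = 0.01)
  for (N in c(64, 128))
    expect_equal(optimal_flip("ventilation", "cartesian", N = N),
                 oracle_cartesian_flip(N), tolerance = 0.01)
  expect_equal(optimal_flip("diffusion", "cartesian", N = 64, Nb = 5),
               oracle_cartesian_flip(64 * 5), tolerance = 0.01)
  expect_error(optimal_flip("ventilation", "spiral"), "arg")
})

test_that("full calibration run recovers every phantom truth parameter", {
  ph <- make_calibration_fids(20, gas_freq_offset_hz = 62, noise_sigma = 0)
  cal <- run_calibration(ph$raw, prescribed_flip_deg = 25)
  expect_length(cal$failures, 0)
  expect_equal(cal$flip_fit$alpha_fit_deg, 20, tolerance = 0.01)
  expect_equal(cal$flip_fit$scale_factor, 25 / 20, tolerance = 1e-3)
  expect_equal(cal$freq_offset_hz, 62, tolerance = 0.5)
  expect_equal(cal$rbc_membrane_ratio, 0.53, tolerance = 0.005)
  expect_equal(cal$tr_ms, 15)
  # TE90 from the truth peak table
  truth_te90 <- 0.45 + 1000 * (90 - (60 - 15)) / (360 * 19 * 34.09)
  expect_equal(cal$te90_ms, truth_te90, tolerance = 0.005)
})

test_that("missing gas FIDs flag the flip and frequency fits as failed", {
  ph <- make_calibration_fids(20, n_gas = 0, noise_sigma = 0)
  cal <- run_calibration(ph$raw, 20)
  expect_true(all(c("flip_angle", "gas_frequency") %in% cal$failures))
  expect_null(cal$flip_fit)
  expect_false(is.null(cal$rbc_membrane_ratio))
})
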