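default_cfg <- function(truth) dixon_config(
  te90_ms = truth$te90_ms, t2stars_ms = truth$t2stars_ms,
  spectro_rbc_mem_ratio = truth$rbc_mem_ratio)

test_that("Dixon separation recovers the truth maps exactly without noise", {
  ph <- make_gasexchange_phantom(shape = c(16, 16, 16))
  sep <- dixon_separate(ph$dissolved, ph$gas, default_cfg(ph$truth), ph$mask)
  inl <- ph$mask$labels == 1L
  expect_lt(max(abs(sep$rbc[inl] -
                      ph$truth$rbc_map[inl] * ph$truth$decay[["rbc"]])), 1e-9)
  expect_lt(max(abs(sep$membrane[inl] -
                      ph$truth$mem_map[inl] * ph$truth$decay[["membrane"]])),
            1e-9)
  expect_lt(sep$zeroed_fraction, 1e-9)
})

test_that("a uniform B0 phase leaves the separation unchanged", {
  ph0 <- make_gasexchange_phantom(b0_phase_map_deg = 0, shape = c(16, 16, 16))
  ph40 <- make_gasexchange_phantom(b0_phase_map_deg = 40, shape = c(16, 16, 16))
  cfg <- default_cfg(ph0$truth)
  s0 <- dixon_separate(ph0$dissolved, ph0$gas, cfg, ph0$mask)
  s40 <- dixon_separate(ph40$dissolved, ph40$gas, cfg, ph40$mask)
  expect_equal(s40$rbc, s0$rbc, tolerance = 1e-9)
  expect_equal(s40$membrane, s0$membrane, tolerance = 1e-9)
  # smooth spatially varying phase field as well
  sh <- c(16, 16, 16)
  yi <- slice.index(array(0, sh), 2)
  field <- 25 * sin(2 * pi * yi / 16)
  phv <- make_gasexchange_phantom(b0_phase_map_deg = field, shape = sh)
  sv <- dixon_separate(phv$dissolved, phv$gas, cfg, phv$mask)
  expect_equal(sv$rbc, s0$rbc, tolerance = 1e-9)
})

test_that("the recovered global RBC:membrane ratio equals the scenario 0.53", {
  ph <- make_gasexchange_phantom(b0_phase_map_deg = 15, shape = c(16, 16, 16))
  gx <- run_gasexchange(list(gas = ph$gas, dissolved = ph$dissolved),
                        default_cfg(ph$truth), ph$mask)
  expect_equal(gx$rbc_mem_ratio, ph$truth$rbc_mem_ratio, tolerance = 1e-6)
  expect_equal(ph$truth$rbc_mem_ratio, 0.53, tolerance = 1e-12)
})

test_that("Dixon output scales linearly with the dissolved input", {
  ph <- make_gasexchange_phantom(shape = c(16, 16, 16))
  cfg <- default_cfg(ph$truth)
  s1 <- dixon_separate(ph$dissolved, ph$gas, cfg, ph$mask)
  dis3 <- ph$dissolved; dis3$data <- dis3$data * 3
  s3 <- dixon_separate(dis3, ph$gas, cfg, ph$mask)
  expect_equal(s3$rbc, 3 * s1$rbc, tolerance = 1e-9)
  expect_equal(s3$membrane, 3 * s1$membrane, tolerance = 1e-9)
})

test_that("intensity corrections apply the decay and flip-angle factors", {
  cfg <- dixon_config(te90_ms = 0.45,
                      t2stars_ms = c(gas = 1.8, membrane = 2.0, rbc = 1.8))
  # sin(20)/sin(0.5) is about 39 (printed rounded in the references)
  expect_equal(unname(cfg$gas_scale), 39.1963, tolerance = 1e-4)
  d <- c(4, 4, 2)
  rbc <- array(1, d); mem <- array(2, d); gas <- array(4, d)
  co <- apply_corrections(rbc, mem, gas, cfg)
  expect_equal(unique(as.vector(co$rbc)), exp(0.45 / 1.8), tolerance = 1e-12)
  expect_equal(unique(as.vector(co$gas)),
               4 * exp(0.45 / 1.8) * cfg$gas_scale, tolerance = 1e-9)
  expect_equal(unique(as.vector(co$rbc2gas)),
               exp(0.45 / 1.8) / (4 * exp(0.45 / 1.8) * cfg$gas_scale),
               tolerance = 1e-12)
  # TE90 0.45 ms, T2* 1.8 ms: correction factor e^0.25
  expect_equal(exp(0.45 / 1.8), exp(0.25))
  # infinite T2*: correction factor 1
  cfg_inf <- dixon_config(te90_ms = 0.45,
                          t2stars_ms = c(gas = 1e12, membrane = 1e12,
                                         rbc = 1e12))
  co2 <- apply_corrections(rbc, mem, gas, cfg_inf)
  expect_equal(unique(as.vector(co2$rbc)), 1, tolerance = 1e-9)
  expect_error(dixon_config(0.45, t2stars_ms = c(gas = -1, membrane = 1,
                                                 rbc = 1)), "T2")
})

test_that("generalized binning uses six bins and eight for membrane", {
  d <- c(10, 10, 2)
  lab <- array(1L, d)
  m <- lung_mask(lab)
  ref <- gasexchange_reference()
  # membrane spanning mu-3s .. mu+5s exercises all eight bins
  mu <- ref$membrane$mu; s <- ref$membrane$sigma
  vals <- array(seq(mu - 3 * s, mu + 5 * s, length.out = prod(d)), d)
  bm <- suppressWarnings(gx_binning(list(membrane = vals), m, ref))$membrane
  expect_length(bm$bin_names, 8)
  expect_equal(sort(unique(bm$labels[lab == 1L])), 1:8)
  expect_equal(sum(bm$percentages), 100, tolerance = 1e-9)
  # rbc at exactly mu: everything in the upper-normal bin of six
  rv <- array(ref$rbc$mu, d)
  br1 <- suppressWarnings(gx_binning(list(rbc = rv), m, ref))$rbc
  expect_length(br1$bin_names, 6)
  expect_equal(unname(br1$percentages[["normal2"]]), 100)
  # rbc default edges start at 0.0026 - 2 * 0.001
  br2 <- suppressWarnings(gx_binning(list(rbc = rv), m, ref))$rbc
  expect_equal(br2$bin_edges[1], 0.0006, tolerance = 1e-12)
  expect_warning(gx_binning(list(rbc = rv), m, ref), "skipped")
})

test_that("gas-exchange SNR subtracts the background mean", {
  d <- c(30, 30, 6)
  lab <- array(0L, d); lab[10:20, 10:20, 2:5] <- 1L
  x <- array(0, d); x[lab == 1L] <- 11
  bg <- which(!xepipe:::morph_cube(lab > 0L, 3, "dilate"))
  set.seed(3)
  noise <- rnorm(length(bg))
  x[bg] <- 1 + (noise - mean(noise)) / stats::sd(noise) * sqrt(2 - pi / 2)
  r <- gx_snr(image_volume(x), lung_mask(lab))
  expect_equal(r$snr, 10, tolerance = 1e-6)
  x2 <- x; x2[lab == 1L] <- mean(x[bg])
  expect_equal(gx_snr(image_volume(x2), lung_mask(lab))$snr, 0,
               tolerance = 1e-9)
})

test_that("radial reconstruction places a point object correctly", {
  n <- 16
  img <- array(0i, c(n, n, n)); img[9, 9, 9] <- 1 + 0i
  vol <- image_volume(img)
  raw <- make_radial_raw(vol, vol, n_spokes = 700, n_samples = n)
  rec <- reconstruct_radial(raw, matrix_size = n)
  g <- rec$gas$data
  pk <- which(Mod(g) == max(Mod(g)), arr.ind = TRUE)
  expect_equal(as.vector(pk), c(9, 9, 9))
  # the sampled k-support is the inscribed ball: peak ~ pi/6 of the DC sum
  expect_equal(Mod(g[9, 9, 9]), pi / 6, tolerance = 0.1)
  # all-zero k-space reconstructs to an all-zero image
  raw0 <- raw; raw0$samples[] <- 0i
  rec0 <- reconstruct_radial(raw0, matrix_size = n)
  expect_true(all(Mod(rec0$gas$data) == 0))
})

test_that("reconstruction conserves energy against a ball-limited DFT oracle", {
  ph <- make_gasexchange_phantom(shape = c(16, 16, 16))
  raw <- make_radial_raw(ph$gas, ph$dissolved, n_spokes = 800, n_samples = 16)
  rec <- reconstruct_radial(raw, matrix_size = 16)
  # oracle: the acquisition samples |k| <= 0.5 only, so compare with the
  # truth image band-limited to the inscribed k-space ball by direct FFT
  ball_limit <- function(x) {
    n <- dim(x)[1]
    f <- (seq_len(n) - 1 - n / 2) / n
    K <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+"))
    sh <- function(a) { i <- c((n / 2 + 1):n, 1:(n / 2)); a[i, i, i] }
    kx <- sh(stats::fft(sh(x)))
    kx[K > 0.5] <- 0
    sh(stats::fft(sh(kx), inverse = TRUE)) / length(x)
  }
  for (ch in c("gas", "dissolved")) {
    tru <- ball_limit(ph[[ch]]$data)
    e_rec <- sum(Mod(rec[[ch]]$data)^2)
    e_tru <- sum(Mod(tru)^2)
    expect_gt(e_rec / e_tru, 0.9)
    expect_lt(e_rec / e_tru, 1.1)
  }
})

test_that("the full gas-exchange chain recovers truth through reconstruction", {
  ph <- make_gasexchange_phantom(b0_phase_map_deg = 20, shape = c(16, 16, 16))
  raw <- make_radial_raw(ph$gas, ph$dissolved, n_spokes = 800, n_samples = 16)
  gx <- run_gasexchange(raw, default_cfg(ph$truth), ph$mask,
                        matrix_size = 16)
  expect_equal(gx$rbc_mem_ratio, 0.53, tolerance = 0.02)
  for (bm in gx$bins)
    expect_equal(sum(bm$percentages), 100, tolerance = 0.01)
})

test_that("volume-input runs recover channel means at 1e-3 without noise", {
  ph <- make_gasexchange_phantom(b0_phase_map_deg = 10, shape = c(16, 16, 16))
  gx <- run_gasexchange(list(gas = ph$gas, dissolved = ph$dissolved),
                        default_cfg(ph$truth), ph$mask)
  inl <- ph$mask$labels == 1L
  # corrected maps equal the t = 0 truth maps
  rbc_corr <- gx$rbc / ph$truth$decay[["rbc"]]
  expect_lt(max(abs(rbc_corr[inl] - ph$truth$rbc_map[inl])) /
              mean(ph$truth$rbc_map[inl]), 1e-3)
  expect_lt(abs(gx$rbc_mem_ratio - 0.53) / 0.53, 1e-3)
})

test_that("missing calibration fields are reported by name", {
  ph <- make_gasexchange_phantom(shape = c(8, 8, 8))
  cal <- structure(list(te90_ms = 0.45), class = "calibration_result")
  expect_error(run_gasexchange(list(gas = ph$gas, dissolved = ph$dissolved),
                               cal, ph$mask), "peaks")
  expect_error(run_gasexchange(list(gas = ph$gas), default_cfg(ph$truth),
                               ph$mask), "dissolved")
})

test_that("reference overrides change bin maps but not corrected intensities", {
  ph <- make_gasexchange_phantom(shape = c(16, 16, 16))
  cfg <- default_cfg(ph$truth)
  vols <- list(gas = ph$gas, dissolved = ph$dissolved)
  g1 <- run_gasexchange(vols, cfg, ph$mask, ref = gasexchange_reference())
  g2 <- run_gasexchange(vols, cfg, ph$mask,
                        ref = gasexchange_reference(rbc = c(0.0135, 5e-4)))
  expect_identical(g1$rbc, g2$rbc)
  expect_identical(g1$maps$rbc2gas, g2$maps$rbc2gas)
  expect_false(identical(g1$bins$rbc$percentages, g2$bins$rbc$percentages))
})
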