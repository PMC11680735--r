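test_that("SNR applies the Rayleigh background correction", {
  d <- c(30, 30, 6)
  lab <- array(0L, d); lab[10:20, 10:20, 2:5] <- 1L
  m <- lung_mask(lab)
  x <- array(0, d)
  x[lab == 1L] <- 10
  # fill exactly the background region the estimator uses (outside the
  # 3-voxel dilation) with values of SD exactly 0.655
  bg <- which(!xepipe:::morph_cube(lab > 0L, 3, "dilate"))
  set.seed(1)
  noise <- rnorm(length(bg))
  x[bg] <- 5 + 0.655 * noise / stats::sd(noise)
  r <- compute_snr(image_volume(x), m, background_margin = 3)
  expect_equal(r$sigma_m, 0.655, tolerance = 1e-6)
  expect_equal(r$sigma_bg, 0.655 / sqrt(2 - pi / 2), tolerance = 1e-6)
  expect_equal(r$snr, 10 * sqrt(2 - pi / 2) / 0.655, tolerance = 1e-6)
  # background-subtracted variant used for gas exchange
  r2 <- compute_snr(image_volume(x), m, variant = "bgsub")
  expect_equal(r2$snr, (10 - r2$s_bg) / r2$sigma_bg, tolerance = 1e-9)
})

test_that("pure Rayleigh noise in the mask gives SNR sqrt(pi/2)", {
  d <- c(40, 40, 8)
  lab <- array(0L, d); lab[15:25, 15:25, 3:6] <- 1L
  set.seed(2)
  x <- array(Mod(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d)))), d)
  r <- compute_snr(image_volume(x), lung_mask(lab))
  # corrected sigma_bg estimates the complex noise SD (1): mean Rayleigh
  # magnitude over it is sqrt(pi/2)
  expect_equal(r$snr, sqrt(pi / 2), tolerance = 0.05)
  expect_equal(r$sigma_bg, 1, tolerance = 0.02)
})

test_that("polynomial bias correction recovers a known quadratic field", {
  ph <- make_ventilation_phantom(bias_spec = list(amplitude = 0.4),
                                 trachea = FALSE)
  bc <- bias_correct(ph$vol, ph$mask, "polynomial")
  inl <- ph$mask$labels == 1L
  resid <- bc$vol$data[inl]            # truth signal is 1.0 everywhere
  expect_lt(stats::sd(resid) / mean(resid), 0.05)
  # identity and flat-field behaviour
  id <- bias_correct(ph$vol, ph$mask, "none")
  expect_identical(id$vol$data, ph$vol$data)
  flat <- make_ventilation_phantom(trachea = FALSE)
  bf <- bias_correct(flat$vol, flat$mask, "polynomial")
  expect_lt(diff(range(bf$field[flat$mask$labels == 1L])), 0.02)
})

test_that("threshold VDP counts defects below 60% of the lung mean", {
  # 100-voxel lung (20 x 5): 25 voxels at 0.1 in one solid 5x5 block at the
  # lung border, 75 at 1.0; the median filter preserves the solid block
  d <- c(22, 7, 1)
  lab <- array(0L, d); lab[2:21, 2:6, 1] <- 1L
  x <- array(0, d); x[lab == 1L] <- 1
  x[2:6, 2:6, 1] <- 0.1                # 25-voxel solid block
  r <- vdp_threshold(image_volume(x), lung_mask(lab))
  expect_equal(r$vdp, 25)
  expect_equal(r$threshold, 0.6 * mean(x[lab == 1L]))
  # uniform signal: nothing below 60% of the mean
  xu <- array(0, d); xu[lab == 1L] <- 0.7
  expect_equal(vdp_threshold(image_volume(xu), lung_mask(lab))$vdp, 0)
  expect_error(vdp_threshold(image_volume(xu), lung_mask(array(0L, d))),
               "empty lung")
})

test_that("the 3x3 median filter removes isolated defect voxels", {
  d <- c(16, 16, 2)
  lab <- array(0L, d); lab[3:14, 3:14, ] <- 1L
  x <- array(0, d); x[lab == 1L] <- 1
  x[8, 8, 1] <- 0                      # single isolated defect voxel
  r <- vdp_threshold(image_volume(x), lung_mask(lab))
  expect_equal(r$vdp, 0)
  # matches the explicit neighbourhood-loop reference implementation
  defect <- lab == 1L & x < 0.6 * mean(x[lab == 1L])
  expect_identical(xepipe:::median3x3_slicewise(defect, lab == 1L),
                   oracle_median3x3(defect, lab == 1L))
})

test_that("threshold VDP equals the brute-force counting oracle on random phantoms", {
  for (s in 1:20) {
    set.seed(s)
    nd <- sample(0:3, 1)
    defects <- replicate(nd, list(center = c(sample(c(10:14, 26:30), 1),
                                             sample(18:26, 1),
                                             sample(5:8, 1)),
                                  radius = runif(1, 2, 5),
                                  intensity_frac = runif(1, 0, 0.5)),
                         simplify = FALSE)
    ph <- make_ventilation_phantom(shape = c(40, 40, 12),
                                   defect_spec = defects,
                                   snr_target = sample(c(15, 30, Inf), 1),
                                   seed = s, trachea = FALSE)
    got <- vdp_threshold(ph$vol, ph$mask)$vdp
    want <- oracle_vdp_threshold(ph$vol$data, ph$mask$labels == 1L)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rescaling divides by the airway-excluded 99th percentile", {
  ph <- make_ventilation_phantom(snr_target = 20, seed = 3)
  norm <- rescale_99(ph$vol, ph$mask)
  excl <- ph$mask$labels == 2L
  q <- unname(stats::quantile(ph$vol$data[!excl], 0.99))
  expect_equal(attr(norm, "scale"), q)
  expect_lte(max(norm$data), 1)
  expect_gte(min(norm$data), 0)
  # constant image maps to 1.0
  cv <- image_volume(array(5, c(6, 6, 2)))
  expect_true(all(rescale_99(cv)$data == 1))
  # empirical quantile check on uniforms
  set.seed(4)
  u <- image_volume(array(runif(1000), c(10, 10, 10)))
  expect_equal(attr(rescale_99(u), "scale"),
               unname(stats::quantile(u$data, 0.99)))
})

test_that("linear binning uses the healthy-reference mu +/- k sigma edges", {
  ref <- healthy_reference(0.68, 0.14)
  d <- c(12, 12, 1)
  lab <- array(0L, d); lab[2:11, 2:11, 1] <- 1L
  m <- lung_mask(lab)
  x <- array(0, d); x[lab == 1L] <- 0.68
  r <- vdp_linear_binning(image_volume(x), m, ref)
  expect_equal(r$bin_map$bin_edges, c(0.40, 0.54, 0.68, 0.82, 0.96))
  expect_equal(unname(r$bin_map$percentages[["normal2"]]), 100)
  expect_equal(r$vdp, 0)
  # 10% of lung voxels at 0.1 -> VDP 10
  idx <- which(lab == 1L)
  x[idx[1:10]] <- 0.1
  r2 <- vdp_linear_binning(image_volume(x), m, ref)
  expect_equal(r2$vdp, 10)
  expect_equal(sum(r2$bin_map$percentages), 100, tolerance = 1e-9)
  # near-zero mu - 2 sigma edges are clipped with a warning
  expect_warning(vdp_linear_binning(image_volume(x), m,
                                    healthy_reference(0.1, 0.2)), "clipped")
})

test_that("hierarchical k-means separates well-defined intensity modes", {
  d <- c(30, 30, 2)
  lab <- array(0L, d); lab[3:28, 3:28, ] <- 1L
  n <- sum(lab == 1L)
  set.seed(5)
  modes <- c(0.05, 0.35, 0.7, 1.0)
  v <- sample(rep(modes, length.out = n)) + rnorm(n, sd = 0.005)
  x <- array(0, d); x[lab == 1L] <- v
  km <- vdp_kmeans(image_volume(x), lung_mask(lab))
  expect_equal(sort(km$centers$image), modes, tolerance = 0.01)
  # bimodal image: defect class captures the low mode
  v2 <- rep(c(0.05, 1), length.out = n)
  x2 <- array(0, d); x2[lab == 1L] <- v2 + seq(0, 1e-3, length.out = n)
  km2 <- vdp_kmeans(image_volume(x2), lung_mask(lab))
  low <- x2[km2$bin_map$labels == 1L]
  expect_true(all(low < 0.1))
  # determinism
  km3 <- vdp_kmeans(image_volume(x), lung_mask(lab))
  expect_identical(km$bin_map$labels, km3$bin_map$labels)
  expect_error(vdp_kmeans(image_volume(x2 * 0 + 0.5), lung_mask(lab)),
               "distinct")
})

test_that("DDI distinguishes compact from scattered defects", {
  d <- c(20, 20, 6)
  lab <- array(1L, d)
  m <- lung_mask(lab)
  none <- compute_ddi(array(FALSE, d), m, "3D")
  expect_equal(none$mean, 0)
  full <- compute_ddi(array(TRUE, d), m, "3D")
  expect_equal(full$mean, 100)
  compact <- array(FALSE, d); compact[8:10, 8:10, 3:5] <- TRUE
  set.seed(6)
  scattered <- array(FALSE, d)
  scattered[sample(prod(d), sum(compact))] <- TRUE
  expect_gt(compute_ddi(compact, m, "3D")$mean,
            compute_ddi(scattered, m, "3D")$mean)
  # direct neighbourhood-count oracle for one voxel
  one <- array(FALSE, d); one[10, 10, 3] <- TRUE
  r1 <- compute_ddi(one, m, "3D", radius_vox = 1)
  expect_equal(r1$mean, 100 * 1 / 27)
  r2d <- compute_ddi(one, m, "2D", radius_vox = 1)
  expect_equal(r2d$mean, 100 * 1 / 9)
  expect_error(compute_ddi(one, m, "3D", radius_vox = 0), "radius")
  out <- array(FALSE, d); out[1, 1, 1] <- TRUE
  m0 <- lung_mask(array(0L, d))
  expect_error(compute_ddi(out, m0, "3D"), "inside the lung")
})

test_that("GLRLM features follow their definitions on constructed images", {
  # constant row of length 8: one run, RP = 1/8
  m <- lung_mask(array(c(rep(1L, 8), rep(0L, 56)), c(8, 8, 1)))
  f <- suppressWarnings(glrlm_features(image_volume(array(0.5, c(8, 8, 1))),
                                       m, directions = 0))
  expect_equal(f$RP, 1 / 8)
  expect_equal(f$LRE, 64)
  # checkerboard: along the axes every run has length 1, so SRE = RP = 1
  # (diagonal directions follow same-colour diagonals and are excluded here)
  cb <- array(0, c(8, 8, 1))
  cb[, , 1] <- (outer(1:8, 1:8, "+") %% 2) * 0.5 + 0.25
  mall <- lung_mask(array(1L, c(8, 8, 1)))
  f2 <- glrlm_features(image_volume(cb), mall, directions = c(0, 90))
  expect_equal(f2$SRE, 1)
  expect_equal(f2$RP, 1)
  expect_error(glrlm_features(image_volume(cb), lung_mask(array(0L, c(8, 8, 1)))),
               "empty mask")
})

test_that("GLRLM matches brute-force run enumeration on a worked 4x4 slice", {
  g <- matrix(c(1, 1, 2, 2,
                3, 1, 2, 4,
                4, 4, 4, 4,
                1, 2, 3, 4), 4, 4, byrow = TRUE)
  # feed through the feature path at 4 levels, direction 0 (along x)
  x <- array((g - 0.5) / 4, c(4, 4, 1))
  vol <- image_volume(x)
  m <- lung_mask(array(1L, c(4, 4, 1)))
  f <- glrlm_features(vol, m, levels = 4, directions = 0)
  # oracle: rle along the same scan lines (runs along the 1st array index)
  or <- oracle_glrlm_0deg(x[, , 1] * 4 + 0.5)
  p <- as.numeric(or); lens <- as.integer(colnames(or)[col(or)])
  nr <- sum(p)
  expect_equal(f$RP, nr / 16)
  expect_equal(f$SRE, sum(p / lens^2) / nr)
  expect_equal(f$LRE, sum(p * lens^2) / nr)
})

test_that("bin maps partition the lung and Eq-3 style identities hold", {
  ph <- make_ventilation_phantom(
    defect_spec = list(list(center = c(20, 35, 6), radius = 4,
                            intensity_frac = 0.1)),
    snr_target = 25, seed = 7)
  vr <- run_ventilation(ph$vol, ph$mask, seed = 1)
  for (bm in vr$bins) {
    expect_equal(sum(bm$percentages), 100, tolerance = 0.01)
    inl <- ph$mask$labels == 1L
    expect_true(all(bm$labels[inl] > 0))
    expect_true(all(bm$labels[!inl] == 0))
  }
  # VDP + 100 VV/TLV = 100 for the threshold method
  expect_equal(vr$vdp_percent$threshold + 100 * vr$vv_ml / vr$tlv_ml, 100,
               tolerance = 1e-9)
})

test_that("enlarging a defect never decreases threshold VDP", {
  base <- list(center = c(20, 35, 6), radius = 3, intensity_frac = 0)
  vdps <- vapply(c(3, 4, 5, 6), function(rad) {
    b <- base; b$radius <- rad
    ph <- make_ventilation_phantom(defect_spec = list(b), trachea = FALSE)
    vdp_threshold(ph$vol, ph$mask)$vdp
  }, 0)
  expect_true(all(diff(vdps) >= 0))
})
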