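# Confocal uptake pipeline stages and brightfield OVB counting.

test_that("cell mask captures disks and rejects speckle noise", {
  expect_warning(m0 <- make_cell_mask(matrix(0, 50, 50)), "constant")
  expect_equal(sum(m0), 0)

  set.seed(61)
  n <- 1000  # sparse field: disks cover ~1.6% of the frame
  img <- matrix(rnorm(n * n, 10, 2), n, n)
  disks <- matrix(0L, n, n)
  centers <- cbind(sample(15:(n - 15), 50, replace = TRUE),
                   sample(15:(n - 15), 50, replace = TRUE))
  off <- expand.grid(dy = -10:10, dx = -10:10)
  off <- off[off$dx^2 + off$dy^2 <= 100, ]
  for (i in 1:50) {
    yy <- centers[i, 1] + off$dy; xx <- centers[i, 2] + off$dx
    disks[cbind(yy, xx)] <- 1L
  }
  img <- img + 100 * disks
  mask <- make_cell_mask(img)
  expect_gte(sum(mask[disks == 1]) / sum(disks), 0.99)
  expect_lte(sum(mask[disks == 0]) / sum(disks == 0), 0.05)

  # isolated bright single pixels fall to the opening step
  speck <- matrix(rnorm(100 * 100, 10, 1), 100, 100)
  speck[cbind(c(20, 50, 80), c(20, 50, 80))] <- 200
  expect_equal(sum(make_cell_mask(speck)), 0)

  # dilation radius can only grow the mask
  m_small <- make_cell_mask(img, r_dil = 1)
  m_big <- make_cell_mask(img, r_dil = 5)
  expect_true(all(m_big[m_small == 1] == 1))
})

test_that("background subtraction is median-based and shift-invariant", {
  img <- matrix(10, 60, 60)
  mask <- matrix(0L, 60, 60)
  mask[20:40, 20:40] <- 1L
  img[mask == 1] <- 100
  out <- subtract_background(img, mask)
  expect_equal(attr(out, "background"), 10)
  expect_equal(unique(out[mask == 1]), 90)
  expect_equal(unique(out[mask == 0]), 0)
  out_shift <- subtract_background(img + 7, mask)
  expect_equal(as.numeric(out_shift), as.numeric(out))
  expect_warning(subtract_background(img, matrix(1L, 60, 60)), "entire")
})

test_that("masked axial profile averages mask pixels and interpolates gaps", {
  red <- matrix(5, 40, 100)
  full <- matrix(1L, 40, 100)
  p <- masked_axial_profile(red, full, 20)
  expect_equal(p$intensity, rep(5, 100))
  expect_equal(diff(p$x_mm)[1], 0.02)

  half <- full; half[, 51:100] <- 0L
  red2 <- red; red2[, 1:50] <- 8
  p2 <- masked_axial_profile(red2, half, 20)
  expect_equal(length(p2$intensity), 100)
  expect_equal(p2$intensity[70], 8)  # interpolated from the covered half
  expect_equal(attr(p2, "interpolated_columns"), 51:100)
  expect_error(masked_axial_profile(red, matrix(0L, 40, 100), 20), "empty")
})

test_that("smoothing and baseline removal preserve peaks, remove trends", {
  flat <- intensity_profile(seq(0.01, 17, 0.02), rep(4, 850))
  out <- smooth_and_baseline(flat)
  expect_lt(max(abs(out$intensity)), 1e-6)

  x <- seq(0.01, 17, 0.02)
  ramp <- 0.5 * x + 3
  peak <- 10 * exp(-(x - 8.5)^2 / (2 * 1.5^2))
  out2 <- smooth_and_baseline(intensity_profile(x, ramp + peak))
  expect_equal(max(out2$intensity), 10, tolerance = 0.05)
  # away from the peak the ramp is gone
  far <- abs(x - 8.5) > 6
  expect_lt(max(abs(out2$intensity[far])), 0.5)

  # pure noise: baseline removal leaves no systematic offset (mean of
  # the output within ~2 SE of zero, SE on the raw noise scale)
  set.seed(71)
  noise <- rnorm(850, 0, 1)
  out3 <- smooth_and_baseline(intensity_profile(x, noise))
  expect_lt(abs(mean(out3$intensity)), 2 * sd(noise) / sqrt(850))

  expect_error(smooth_and_baseline(intensity_profile(c(0.1, 0.2), c(1, 2))),
               "window_mm")
})

test_that("Gaussian peak fit recovers exact parameters and rejects noise", {
  p <- gaussian_profile(a = 10, xc = 8.5, sigma = 1.2)
  fit <- fit_gaussian_peak(p)
  expect_true(fit$success)
  expect_equal(fit$center_mm, 8.5, tolerance = 1e-6)
  expect_equal(fit$sigma_mm, 1.2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 10, tolerance = 1e-6)

  set.seed(81)
  flat <- intensity_profile(seq(0.01, 17, 0.02), rnorm(850, 0, 1))
  expect_false(fit_gaussian_peak(flat, noise_sd = 1)$success)

  hits <- vapply(1:50, function(seed) {
    set.seed(seed)
    x <- seq(0.01, 17, 0.02)
    y <- 10 * exp(-(x - 8.5)^2 / (2 * 1.2^2)) + rnorm(850, 0, 1)
    f <- fit_gaussian_peak(intensity_profile(x, y), noise_sd = 1)
    f$success && abs(f$center_mm - 8.5) < 0.2 &&
      abs(f$sigma_mm / 1.2 - 1) < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("TFI integrates the correct window with fallback and clipping", {
  zero <- intensity_profile(seq(0.01, 17, 0.02), rep(0, 850))
  ok_peak <- fit_gaussian_peak(gaussian_profile(10, 8.5, 1.2))
  expect_equal(total_fluorescence_intensity(zero, ok_peak)$tfi, 0)

  # +/- 2 sigma over a unit-amplitude, sigma = 1 mm Gaussian:
  # sqrt(2 pi) erf(sqrt(2)) = 2.3926
  dense <- gaussian_profile(1, 8.5, 1, dx = 0.002)
  pk <- fit_gaussian_peak(dense)
  res <- total_fluorescence_intensity(dense, pk)
  expect_equal(res$method, "gaussian-window")
  expect_equal(res$tfi, 2.392576, tolerance = 1e-4)
  total <- sqrt(2 * pi)
  expect_equal(res$tfi / total, 0.9545, tolerance = 0.001)

  failed <- structure(list(center_mm = NA, sigma_mm = NA, amplitude = NA,
                           offset = NA, success = FALSE, reason = "test"),
                      class = "peak_fit")
  res_fb <- total_fluorescence_intensity(zero, failed)
  expect_equal(res_fb$method, "central-window")
  expect_equal(res_fb$window, c(5.005, 12.005), tolerance = 0.02)

  edge <- structure(list(center_mm = 0.5, sigma_mm = 1, amplitude = 5,
                         offset = 0, success = TRUE, reason = "ok"),
                    class = "peak_fit")
  expect_warning(total_fluorescence_intensity(dense, edge), "clipped")
  outside <- structure(list(center_mm = 40, sigma_mm = 1, amplitude = 5,
                            offset = 0, success = TRUE, reason = "ok"),
                       class = "peak_fit")
  expect_error(total_fluorescence_intensity(dense, outside), "outside")
})

test_that("the full pipeline is deterministic, linear, and localized", {
  spec <- generator_spec(123)
  m <- gen_confocal_map(spec)
  r1 <- quantify_uptake(m)
  r2 <- quantify_uptake(m)
  expect_identical(r1$tfi, r2$tfi)
  expect_identical(r1$peak$center_mm, r2$peak$center_mm)

  truth <- attr(m, "truth")
  expect_equal(r1$tfi, truth$tfi_2sigma, tolerance = 0.1)
  expect_equal(r1$peak$center_mm, truth$center_mm, tolerance = 0.2)

  # doubling the planted amplitude doubles TFI
  m2 <- gen_confocal_map(spec, amplitude = 2 * spec$uptake_amplitude)
  r_dbl <- quantify_uptake(m2)
  expect_equal(r_dbl$tfi / r1$tfi, 2, tolerance = 0.05)

  # moving the stripe moves the fitted center with it
  spec_moved <- generator_spec(123, uptake_center_mm = 11)
  r_mv <- quantify_uptake(gen_confocal_map(spec_moved))
  expect_equal(r_mv$peak$center_mm - r1$peak$center_mm, 2.5, tolerance = 0.2)
})

test_that("OVB counting recovers planted spots and converts units", {
  imgs <- gen_brightfield_ovb(generator_spec(5))
  conc <- count_ovb(imgs, 0.5)
  truth <- attr(imgs, "truth")
  expect_equal(attr(conc, "count"), truth$count)
  expect_equal(as.numeric(conc), truth$concentration_per_ml)

  blank <- list(matrix(rnorm(200 * 200, 200, 5), 200, 200))
  expect_equal(attr(count_ovb(blank, 0.5), "count"), 0)

  # doubling the planted count doubles the concentration
  imgs2 <- gen_brightfield_ovb(generator_spec(5, ovb_count = 20))
  conc2 <- count_ovb(imgs2, 0.5)
  expect_equal(as.numeric(conc2) / as.numeric(conc), 2)

  # 10 spots in a 160 x 160 um field, 50 um deep -> 7.8e6 /mL
  ten <- gen_brightfield_ovb(generator_spec(9, ovb_shape_px = c(1000, 1000),
                                            ovb_pixel_size_um = 0.16))
  c10 <- count_ovb(ten, 0.16)
  expect_equal(as.numeric(c10), 7.8e6, tolerance = 0.01)
  expect_error(count_ovb(list(), 0.5), "non-empty")
})

test_that("OVB detection limit formula is unit-correct", {
  expect_equal(ovb_detection_limit(2e4, 1, 50), 1e6)
  expect_equal(ovb_detection_limit(2e4, 1, 100), 5e5)
  expect_equal(ovb_detection_limit(2e4, 4, 50), 2.5e5)
})
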