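# Size-distribution analytics and the camera-level detection model.

test_that("size_distribution validates its invariants", {
  expect_error(size_distribution(c(300, 200), c(1, 1)), "increasing")
  expect_error(size_distribution(c(200, 300), c(1, -1)), ">= 0")
  expect_error(size_distribution(numeric(0), numeric(0)), "empty")
  zero <- size_distribution(c(200, 300), c(0, 0))
  expect_equal(total_concentration(zero), 0)
  expect_error(modal_size(zero), "zero total")
})

test_that("modal size picks the max bin, ties toward smaller diameter", {
  expect_equal(modal_size(size_distribution(300, 5e8)), 300)
  two <- size_distribution(c(200, 300, 400), c(1e8, 5e7, 1e8))
  expect_equal(modal_size(two), 200)
  d <- gen_size_distribution(generator_spec())
  expect_lt(abs(modal_size(d) - attr(d, "truth")$mode_nm), 10)  # one bin
})

test_that("mean size is the concentration-weighted mean", {
  expect_equal(mean_size(size_distribution(300, 1e8)), 300)
  expect_equal(mean_size(size_distribution(c(200, 400), c(1, 1))), 300)
  d <- gen_size_distribution(generator_spec())
  expect_equal(mean_size(d), attr(d, "truth")$mean_nm, tolerance = 0.02)
})

test_that("percentiles interpolate and match the planted lognormal", {
  expect_equal(percentile_size(size_distribution(300, 1), 25), 300)
  unif <- size_distribution(seq(100, 600, 10), rep(1, 51))
  expect_equal(percentile_size(unif, 50), 350, tolerance = 10)
  d <- gen_size_distribution(generator_spec())
  expect_equal(percentile_size(d, 95), attr(d, "truth")$quantile(0.95),
               tolerance = 0.03)
  q <- c(5, 25, 50, 75, 95)
  expect_true(all(diff(percentile_size(d, q)) > 0))
  expect_error(percentile_size(d, 0), "q must")
})

test_that("cumulative distribution is nondecreasing and ends at 100", {
  two <- size_distribution(c(200, 400), c(1, 1))
  cd <- cumulative_distribution(two)
  expect_equal(cd$cumulative_percent, c(50, 100))
  set.seed(21)
  for (i in 1:5) {
    cd <- cumulative_distribution(random_distribution())
    expect_true(all(diff(cd$cumulative_percent) >= 0))
    expect_equal(cd$cumulative_percent[nrow(cd)], 100, tolerance = 1e-9)
  }
})

test_that("percentile_size and fraction_below are mutual inverses", {
  set.seed(31)
  for (i in 1:10) {
    d <- random_distribution()
    for (q in c(10, 35, 50, 88, 95)) {
      expect_equal(fraction_below(d, percentile_size(d, q)), q,
                   tolerance = 1e-6)
    }
  }
  d <- random_distribution()
  expect_equal(fraction_below(d, 10), 0)
  expect_equal(fraction_below(d, 2000), 100)
})

test_that("volume weighting scales bins by d^3 and shifts the mode up", {
  two <- size_distribution(c(200, 400), c(1e8, 1e8))
  vw <- volume_weighted(two)
  expect_equal(vw$number_concentration[2] / vw$number_concentration[1], 8)
  d <- gen_size_distribution(generator_spec())
  expect_gt(modal_size(volume_weighted(d)), modal_size(d))
})

test_that("gas volume fraction is correct, linear, and d^3-scaled", {
  expect_equal(gas_volume_fraction(size_distribution(c(200, 300), c(0, 0))), 0)
  # frozen oracle: (pi/6)(6e-5 cm)^3 * 1e10 * 100
  expect_equal(gas_volume_fraction(size_distribution(600, 1e10)), 0.1131,
               tolerance = 1e-3)
  d <- gen_size_distribution(generator_spec())
  d2 <- size_distribution(d$bin_centers, 2 * d$number_concentration)
  expect_equal(gas_volume_fraction(d2), 2 * gas_volume_fraction(d))
  dil <- size_distribution(2 * d$bin_centers, d$number_concentration)
  expect_equal(gas_volume_fraction(dil), 8 * gas_volume_fraction(d))
})

test_that("flotation reweighting shifts the population toward larger sizes", {
  d <- gen_size_distribution(generator_spec())
  none <- apply_flotation(d, 0, 400e-6)
  expect_equal(total_concentration(none), 0)
  # long enough that every bin floats up completely
  all_up <- apply_flotation(d, 1e9, 400e-6)
  expect_equal(all_up$number_concentration, d$number_concentration)
  shifted <- apply_flotation(d, 3600, 400e-6)
  expect_true(all(shifted$number_concentration <=
                    d$number_concentration + 1e-12))
  expect_gte(modal_size(shifted), modal_size(d))
  # analytic oracle: below the full-transfer cutoff the transfer weight
  # is d^2, so the lognormal mode moves from median e^(-s^2) to
  # median e^(+s^2)
  spec <- generator_spec()
  expect_lt(abs(modal_size(shifted) -
                  spec$bubble_median_nm * exp(spec$bubble_sigma_ln^2)), 10)
})

test_that("camera settings pin the documented levels and reject others", {
  l3 <- camera_setting(3)
  expect_equal(c(l3$gain, l3$shutter_time), c(15, 0.33))
  expect_equal(camera_setting(4)$shutter_time, 0.58)
  expect_equal(camera_setting(5)$shutter_time, 1.13)
  expect_equal(camera_setting(8)$shutter_time, 7.93)
  l12 <- camera_setting(12)
  expect_equal(c(l12$gain, l12$shutter_time, l12$histogram_upper_limit),
               c(146, 30, 11529))
  expect_error(camera_setting(7), "supply")
  expect_equal(camera_setting(7, gain = 15, shutter_time = 5,
                              histogram_upper_limit = 16380)$shutter_time, 5)
  expect_error(camera_setting(0), "1..16")
})

test_that("detection model separates bubbles from liposomes by level", {
  pop <- single_bin_pair(90, bubbles_per_ml = 1e9, liposomes_per_ml = 1e9)
  lip <- single_bin_pair(90, liposomes_per_ml = 1e9)
  # zero threshold returns everything
  full <- simulate_detection(pop, camera_setting(3), detection_threshold = 0)
  expect_equal(total_concentration(full), 2e9)
  # liposome-only population invisible at the low levels, visible at 12
  for (lev in c(3, 4, 5))
    expect_equal(total_concentration(simulate_detection(lip,
                                                        camera_setting(lev))),
                 0)
  expect_equal(total_concentration(simulate_detection(lip,
                                                      camera_setting(12))),
               1e9)
  # bubble of the same size already visible at level 3
  bub <- single_bin_pair(90, bubbles_per_ml = 1e9)
  expect_equal(total_concentration(simulate_detection(bub,
                                                      camera_setting(3))),
               1e9)
})

test_that("detection is monotone in gain, shutter, and index contrast", {
  mp <- gen_mixed_population(generator_spec())
  detected_bins <- function(camera)
    which(simulate_detection(mp, camera)$number_concentration > 0)
  base <- detected_bins(camera_setting(3))
  more_gain <- detected_bins(camera_setting(3, gain = 150,
                                            shutter_time = 0.33,
                                            histogram_upper_limit = 16380))
  more_shutter <- detected_bins(camera_setting(5))
  expect_true(all(base %in% more_gain))
  expect_true(all(base %in% more_shutter))
})

test_that("DLS-style helper is intensity-weighted and marked approximate", {
  mono <- size_distribution(300, 1e9)
  expect_equal(intensity_weighted_harmonic_mean(mono), 300)
  d <- gen_size_distribution(generator_spec())
  # intensity weighting (d^6) must pull the estimate above the number mean
  expect_gt(intensity_weighted_harmonic_mean(d), mean_size(d))
})
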