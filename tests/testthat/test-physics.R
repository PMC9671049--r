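# Closed-form physics: flotation, scattering, beam spread, spacing.

test_that("terminal rise velocity follows Stokes d^2 scaling and limits", {
  expect_equal(terminal_rise_velocity(0), 0)
  # frozen oracle: g d^2 drho / (18 mu) at d = 458 nm, drho = 990
  expect_equal(terminal_rise_velocity(458e-9, water()), 1.271665e-7,
               tolerance = 1e-6)
  set.seed(11)
  d <- runif(20, 50e-9, 1e-6)
  a <- runif(20, 0.5, 3)
  expect_equal(terminal_rise_velocity(a * d) / terminal_rise_velocity(d),
               a^2, tolerance = 1e-10)
  expect_error(terminal_rise_velocity(-1e-9), "diameter")
  expect_error(medium_properties(medium_density = 5, gas_density = 8),
               "exceed")
})

test_that("rise distance and its inversion round-trip", {
  expect_equal(rise_distance(500e-9, 0), 0)
  expect_equal(rise_distance(458e-9, 3600, water()), 457.8e-6,
               tolerance = 1e-4)
  expect_equal(rise_distance(324e-9, 3600, water()), 229.1e-6,
               tolerance = 1e-3)
  expect_equal(min_diameter_for_distance(0, 3600), 0)
  expect_equal(min_diameter_for_distance(400e-6, 3600, water()), 428.1e-9,
               tolerance = 1e-4)
  d <- seq(100e-9, 1000e-9, length.out = 25)
  back <- min_diameter_for_distance(rise_distance(d, 3600), 3600)
  expect_equal(back, d, tolerance = 1e-12)
  expect_error(min_diameter_for_distance(1e-4, 0), "duration")
})

test_that("drag constant is configurable", {
  # doubling the denominator halves the velocity
  expect_equal(terminal_rise_velocity(300e-9, drag_constant = 36),
               terminal_rise_velocity(300e-9) / 2)
})

test_that("Rayleigh cross-section has d^6 / lambda^-4 scaling and zeros", {
  matched <- optical_context(n_medium = 1.33, n_particle = 1.33)
  expect_equal(rayleigh_cross_section(30e-9, matched), 0)
  s1 <- rayleigh_cross_section(20e-9, bubble_optics())
  s2 <- rayleigh_cross_section(40e-9, bubble_optics())
  expect_equal(s2 / s1, 64, tolerance = 1e-12)
  s_blue <- rayleigh_cross_section(30e-9, bubble_optics(wavelength = 400e-9))
  s_red <- rayleigh_cross_section(30e-9, bubble_optics(wavelength = 800e-9))
  expect_equal(s_blue / s_red, 16, tolerance = 1e-12)
  expect_warning(rayleigh_cross_section(100e-9,
                                        bubble_optics(wavelength = 200e-9)),
                 "Rayleigh regime")
})

test_that("bubble/liposome scattering contrast is ~46 and size-invariant", {
  # frozen oracle: ((mb^2-1)/(mb^2+2))^2 / ((ml^2-1)/(ml^2+2))^2
  expect_equal(scattering_ratio(100e-9, bubble_optics(), liposome_optics()),
               46.31476, tolerance = 1e-6)
  for (d in c(100e-9, 300e-9, 600e-9))
    for (lam in c(405e-9, 488e-9, 633e-9))
      expect_equal(scattering_ratio(d, bubble_optics(lam), liposome_optics(lam)),
                   46.31476, tolerance = 1e-6)
  expect_equal(scattering_ratio(1e-7, bubble_optics(), bubble_optics()), 1)
  expect_error(scattering_ratio(1e-7, bubble_optics(wavelength = 488e-9),
                                liposome_optics(wavelength = 633e-9)),
               "share")
})

test_that("beam half-angle and width match the printed geometry", {
  spec <- transducer_spec()
  expect_equal(beam_half_angle(spec, 0), 0)
  # frozen oracle: asin(k c / (f D))
  expect_equal(beam_half_angle(spec, 0.56), 0.0580413, tolerance = 1e-5)
  expect_equal(beam_half_angle(spec, 1.08), 0.1121087, tolerance = 1e-5)
  expect_equal(beam_width(spec, 0.56) * 1e3, 2.3243, tolerance = 1e-4)
  expect_equal(beam_width(spec, 1.08) * 1e3, 4.5032, tolerance = 1e-4)
  zero_z <- transducer_spec(standoff_distance = 1e-12)
  expect_lt(beam_width(zero_z, 0.56), 1e-12)
  expect_error(beam_half_angle(transducer_spec(center_frequency = 1e3), 1),
               "undefined")
})

test_that("beam width is monotone in k and small-angle limit holds", {
  spec <- transducer_spec()
  k <- seq(0.1, 1.2, 0.1)
  expect_true(all(diff(beam_width(spec, k)) > 0))
  # alpha -> k c/(f D) when the argument is small
  tiny <- 0.05 * spec$center_frequency * spec$element_diameter /
    spec$sound_speed
  arg <- tiny * spec$sound_speed /
    (spec$center_frequency * spec$element_diameter)
  expect_equal(beam_half_angle(spec, tiny) / arg, 1, tolerance = 0.01)
})

test_that("Laplace pressure, interbubble distance, and l/d behave", {
  expect_equal(laplace_pressure(50e-9, 0), 0)
  expect_equal(laplace_pressure(50e-9, 0.072), 2.88e6)
  expect_equal(laplace_pressure(100e-9, 0.072),
               laplace_pressure(50e-9, 0.072) / 2)
  expect_error(laplace_pressure(0, 0.072), "radius")

  expect_equal(interbubble_distance(1e15), 10e-6)  # 1e9 /mL -> 10 um
  expect_equal(interbubble_distance(1), 1)
  expect_equal(interbubble_distance(8e15), interbubble_distance(1e15) / 2)
  expect_error(interbubble_distance(0), "number_density")

  expect_equal(l_over_d(1e15, 300e-9), 10e-6 / 300e-9)
  expect_error(l_over_d(1e15, 0), "mean_diameter")
})

test_that("predicted surface density is linear and unit-correct", {
  expect_equal(predicted_surface_density(0, 0.4e-3), 0)
  expect_equal(predicted_surface_density(1e10, 0.4e-3), 4)
  expect_equal(predicted_surface_density(2.5e8, 0.4e-3), 0.1)
})

test_that("flotation transfer fraction is bounded and monotone", {
  expect_equal(flotation_transfer_fraction(500e-9, 0, 400e-6), 0)
  expect_equal(flotation_transfer_fraction(458e-9, 3600, 400e-6), 1)
  expect_equal(flotation_transfer_fraction(324e-9, 3600, 400e-6), 0.5728,
               tolerance = 1e-3)
  d <- seq(50e-9, 1000e-9, length.out = 40)
  f <- flotation_transfer_fraction(d, 3600, 400e-6)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  f_t <- vapply(seq(0, 7200, length.out = 10),
                function(t) flotation_transfer_fraction(300e-9, t, 400e-6),
                numeric(1))
  expect_true(all(diff(f_t) >= 0))
  expect_error(flotation_transfer_fraction(300e-9, 100, 0), "channel_height")
})
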