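# Closed-form physical models used to isolate and discriminate nanobubbles:
# Stokes flotation, Rayleigh scattering, far-field beam spread, Laplace
# pressure, interbubble spacing, and predicted surface density.

#' Physical properties of the suspending medium
#'
#' Container for the constants entering the Stokes terminal-rise model:
#' dynamic viscosity, the densities of medium and gas core, and
#' gravitational acceleration. Defaults describe perfluoropropane-core
#' bubbles in water: `viscosity = 8.9e-4` Pa s, density difference
#' `medium_density - gas_density = 990` kg/m^3.
#'
#' @param viscosity Dynamic viscosity of the fluid, Pa s.
#' @param medium_density Density of the suspending medium, kg/m^3.
#' @param gas_density Density of the gas core, kg/m^3.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return An object of class `medium_properties`.
#' @examples
#' medium_properties()
#' medium_properties(viscosity = 1e-3)
#' @export
medium_properties <- function(viscosity = 8.9e-4, medium_density = 998,
                              gas_density = 8, gravity = 9.81) {
  stopifnot(is.numeric(viscosity), length(viscosity) == 1L,
            is.numeric(medium_density), length(medium_density) == 1L,
            is.numeric(gas_density), length(gas_density) == 1L,
            is.numeric(gravity), length(gravity) == 1L)
  if (viscosity <= 0 || medium_density <= 0 || gas_density <= 0 || gravity <= 0)
    stop("all medium properties must be strictly positive")
  if (medium_density <= gas_density)
    stop("medium_density must exceed gas_density (buoyant particle)")
  structure(list(viscosity = viscosity, medium_density = medium_density,
                 gas_density = gas_density, gravity = gravity),
            class = "medium_properties")
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("Medium: mu =", x$viscosity, "Pa s, delta-rho =",
      x$medium_density - x$gas_density, "kg/m^3, g =", x$gravity, "m/s^2\n")
  invisible(x)
}

#' Optical context for Rayleigh scattering
#'
#' Wavelength and refractive indices entering the Rayleigh cross-section.
#' The relative index m = n_particle/n_medium is always derived, never
#' stored. Defaults: 488 nm illumination (NTA laser) in water (n = 1.33).
#'
#' @param wavelength Incident wavelength, m.
#' @param n_medium Refractive index of the medium (>= 1).
#' @param n_particle Refractive index of the particle (> 0); 1.00 for a
#'   gas core, about 1.38 for an aqueous-filled liposome.
#' @return An object of class `optical_context`.
#' @examples
#' bubble_optics()
#' liposome_optics()
#' @export
optical_context <- function(wavelength = 488e-9, n_medium = 1.33,
                            n_particle = 1.00) {
  stopifnot(is.numeric(wavelength), is.numeric(n_medium), is.numeric(n_particle))
  if (wavelength <= 0) stop("wavelength must be positive")
  if (n_medium < 1) stop("n_medium must be >= 1")
  if (n_particle <= 0) stop("n_particle must be > 0")
  structure(list(wavelength = wavelength, n_medium = n_medium,
                 n_particle = n_particle),
            class = "optical_context")
}

#' @rdname optical_context
#' @export
bubble_optics <- function(wavelength = 488e-9, n_medium = 1.33)
  optical_context(wavelength, n_medium, n_particle = 1.00)

#' @rdname optical_context
#' @export
liposome_optics <- function(wavelength = 488e-9, n_medium = 1.33)
  optical_context(wavelength, n_medium, n_particle = 1.38)

#' @export
print.optical_context <- function(x, ...) {
  cat("Optics: lambda =", x$wavelength * 1e9, "nm, n_medium =", x$n_medium,
      ", n_particle =", x$n_particle,
      sprintf("(m = %.4f)\n", x$n_particle / x$n_medium))
  invisible(x)
}

#' Unfocused transducer specification
#'
#' Geometry and acoustics of a plane circular element used for the
#' far-field beam-spread model. Defaults describe a 2.25 MHz, 6.35 mm
#' element driven through a 20 mm stand-off in water (c = 1480 m/s).
#'
#' @param center_frequency Center frequency, Hz.
#' @param element_diameter Active element diameter, m.
#' @param sound_speed Speed of sound in the coupling medium, m/s.
#' @param standoff_distance Distance from the element face to the target
#'   plane, m.
#' @return An object of class `transducer_spec`.
#' @examples
#' transducer_spec()
#' @export
transducer_spec <- function(center_frequency = 2.25e6,
                            element_diameter = 6.35e-3,
                            sound_speed = 1480,
                            standoff_distance = 20e-3) {
  vals <- c(center_frequency, element_diameter, sound_speed, standoff_distance)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all transducer parameters must be strictly positive")
  structure(list(center_frequency = center_frequency,
                 element_diameter = element_diameter,
                 sound_speed = sound_speed,
                 standoff_distance = standoff_distance),
            class = "transducer_spec")
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat("Transducer:", x$center_frequency / 1e6, "MHz, D =",
      x$element_diameter * 1e3, "mm, c =", x$sound_speed,
      "m/s, stand-off =", x$standoff_distance * 1e3, "mm\n")
  invisible(x)
}

#' Terminal flotation (rise) velocity of a buoyant sphere
#'
#' Stokes terminal velocity U = g d^2 (rho_medium - rho_gas) / (K mu) for
#' a small rigid sphere, the model governing centrifugal size isolation
#' of nanobubbles. The drag denominator K defaults to the Stokes value 18
#' but is exposed because shelled bubbles can deviate from rigid-sphere
#' drag.
#'
#' @param diameter Particle diameter, m (vectorized, >= 0).
#' @param medium A [medium_properties()] object.
#' @param drag_constant Denominator constant of the Stokes form
#'   (default 18).
#' @return Terminal rise velocity, m/s.
#' @examples
#' terminal_rise_velocity(458e-9)            # ~1.27e-7 m/s
#' terminal_rise_velocity(458e-9) * 3600     # ~458 um in 60 min
#' @export
terminal_rise_velocity <- function(diameter, medium = medium_properties(),
                                   drag_constant = 18) {
  stopifnot(inherits(medium, "medium_properties"), is.numeric(diameter))
  if (any(diameter < 0)) stop("diameter must be >= 0")
  if (drag_constant <= 0) stop("drag_constant must be positive")
  drho <- medium$medium_density - medium$gas_density
  medium$gravity * diameter^2 * drho / (drag_constant * medium$viscosity)
}

#' Distance risen at terminal velocity
#'
#' Vertical distance a bubble of a given diameter rises in `duration`
#' seconds, assuming terminal velocity from t = 0 (the inertial
#' transient for sub-micron particles is sub-microsecond).
#'
#' @inheritParams terminal_rise_velocity
#' @param duration Flotation time, s (>= 0).
#' @return Distance, m.
#' @export
rise_distance <- function(diameter, duration, medium = medium_properties(),
                          drag_constant = 18) {
  if (any(duration < 0)) stop("duration must be >= 0")
  terminal_rise_velocity(diameter, medium, drag_constant) * duration
}

#' Smallest diameter that rises a given distance in a given time
#'
#' Closed-form inversion of [rise_distance()]:
#' d = sqrt(K mu s / (g delta-rho t)).
#'
#' @param distance Target rise distance, m (>= 0).
#' @inheritParams rise_distance
#' @return Diameter, m. Round-trips with [rise_distance()] to machine
#'   precision.
#' @export
min_diameter_for_distance <- function(distance, duration,
                                      medium = medium_properties(),
                                      drag_constant = 18) {
  stopifnot(inherits(medium, "medium_properties"))
  if (any(distance < 0)) stop("distance must be >= 0")
  if (any(duration <= 0)) stop("duration must be > 0")
  drho <- medium$medium_density - medium$gas_density
  sqrt(drag_constant * medium$viscosity * distance /
         (medium$gravity * drho * duration))
}

rayleigh_index_factor <- function(m) ((m^2 - 1) / (m^2 + 2))^2

#' Rayleigh scattering cross-section
#'
#' sigma_s = (2 pi^5 / 3) d^6 / lambda^4 ((m^2 - 1)/(m^2 + 2))^2 with
#' m = n_particle/n_medium — valid in the small-particle limit where the
#' size parameter x = pi d / lambda is well below 1. A warning is issued
#' when x > 0.3 (the conventional edge of the Rayleigh regime); the
#' value is still returned.
#'
#' @param diameter Particle diameter, m (vectorized).
#' @param optics An [optical_context()].
#' @return Scattering cross-section, m^2. Zero iff the particle is
#'   index-matched (m = 1).
#' @examples
#' rayleigh_cross_section(100e-9, bubble_optics())
#' @export
rayleigh_cross_section <- function(diameter, optics = bubble_optics()) {
  stopifnot(inherits(optics, "optical_context"), is.numeric(diameter))
  if (any(diameter < 0)) stop("diameter must be >= 0")
  m <- optics$n_particle / optics$n_medium
  if (m <= 0) stop("relative refractive index must be positive")
  x <- pi * diameter / optics$wavelength
  if (any(x > 0.3))
    warning("size parameter x = pi*d/lambda exceeds 0.3; ",
            "outside the strict Rayleigh regime")
  (2 * pi^5 / 3) * diameter^6 / optics$wavelength^4 * rayleigh_index_factor(m)
}

#' Scattering contrast between two particle types
#'
#' Ratio of Rayleigh cross-sections of two particles of the same size in
#' the same medium and illumination — e.g. a gas-filled bubble versus an
#' aqueous liposome. The ratio depends only on the two relative indices,
#' so it is independent of diameter and wavelength; with n = 1.00 vs
#' 1.38 in water (1.33) it is about 46, the contrast that lets NTA at a
#' low camera level see bubbles but not liposomes.
#'
#' @param diameter Particle diameter, m (the ratio does not depend on it).
#' @param optics_a,optics_b [optical_context()] objects sharing
#'   wavelength and `n_medium`.
#' @return Dimensionless ratio sigma_a / sigma_b.
#' @examples
#' scattering_ratio(100e-9, bubble_optics(), liposome_optics())
#' @export
scattering_ratio <- function(diameter, optics_a, optics_b) {
  stopifnot(inherits(optics_a, "optical_context"),
            inherits(optics_b, "optical_context"))
  if (!isTRUE(all.equal(optics_a$wavelength, optics_b$wavelength)) ||
      !isTRUE(all.equal(optics_a$n_medium, optics_b$n_medium)))
    stop("optical contexts must share wavelength and n_medium")
  fa <- rayleigh_index_factor(optics_a$n_particle / optics_a$n_medium)
  fb <- rayleigh_index_factor(optics_b$n_particle / optics_b$n_medium)
  if (fb == 0) stop("reference particle is index-matched; ratio undefined")
  rep_len(fa / fb, length(diameter))
}

#' Far-field beam half-angle of a plane circular element
#'
#' alpha = asin(k c / (f D)). The constant k selects the contour at
#' which spread is measured: k = 0.56 for the -6 dB (half-pressure)
#' contour, 1.08 for -20 dB.
#'
#' @param spec A [transducer_spec()].
#' @param k Beam-spread constant (dimensionless, >= 0).
#' @return Half-angle, rad.
#' @examples
#' beam_half_angle(transducer_spec(), k = 0.56)
#' @export
beam_half_angle <- function(spec = transducer_spec(), k = 0.56) {
  stopifnot(inherits(spec, "transducer_spec"), is.numeric(k))
  if (any(k < 0)) stop("k must be >= 0")
  arg <- k * spec$sound_speed / (spec$center_frequency * spec$element_diameter)
  if (any(arg >= 1))
    stop("beam-spread argument k*c/(f*D) >= 1: half-angle undefined")
  asin(arg)
}

#' Predicted beam width at the stand-off plane
#'
#' Width of the diverging beam at the stand-off distance z,
#' 2 z tan(alpha), with alpha from [beam_half_angle()]. For the default
#' transducer (2.25 MHz, 6.35 mm, water, z = 20 mm) this gives 2.3 mm at
#' -6 dB (k = 0.56) and 4.5 mm at -20 dB (k = 1.08).
#'
#' @inheritParams beam_half_angle
#' @return Beam width, m.
#' @examples
#' beam_width(transducer_spec(), k = 0.56) * 1e3  # mm
#' beam_width(transducer_spec(), k = 1.08) * 1e3
#' @export
beam_width <- function(spec = transducer_spec(), k = 0.56) {
  2 * spec$standoff_distance * tan(beam_half_angle(spec, k))
}

#' Laplace pressure of a gas-liquid interface
#'
#' Excess internal pressure delta-P = 2 sigma / r of a curved interface;
#' it grows as bubbles shrink and drives small-bubble dissolution.
#'
#' @param radius Bubble radius, m (> 0).
#' @param surface_tension Interfacial tension, N/m (>= 0); 0.072 for a
#'   clean air-water interface, much less for a lipid shell.
#' @return Pressure, Pa.
#' @examples
#' laplace_pressure(50e-9, 0.072)  # 2.88 MPa
#' @export
laplace_pressure <- function(radius, surface_tension) {
  if (any(radius <= 0)) stop("radius must be > 0")
  if (any(surface_tension < 0)) stop("surface_tension must be >= 0")
  2 * surface_tension / radius
}

#' Mean interbubble distance from number density
#'
#' Nearest-neighbour scale l = n^(-1/3) for particles at volume number
#' density n. Small l (relative to diameter) is hypothesized to shield
#' bubbles against gas diffusion.
#'
#' @param number_density Particles per m^3 (> 0). Multiply a per-mL
#'   concentration by 1e6 to convert.
#' @return Distance, m.
#' @examples
#' interbubble_distance(1e15)  # 10 um at 1e9 /mL
#' @export
interbubble_distance <- function(number_density) {
  if (any(number_density <= 0)) stop("number_density must be > 0")
  number_density^(-1 / 3)
}

#' Interbubble spacing to diameter ratio
#'
#' l/d with l = n^(-1/3): the dimensionless spacing used to interpret
#' concentration-dependent bubble stability.
#'
#' @param number_density Particles per m^3 (> 0).
#' @param mean_diameter Mean bubble diameter, m (> 0).
#' @return Dimensionless ratio.
#' @export
l_over_d <- function(number_density, mean_diameter) {
  if (any(mean_diameter <= 0)) stop("mean_diameter must be > 0")
  interbubble_distance(number_density) / mean_diameter
}

#' Predicted bubble surface density after complete flotation
#'
#' Upper-bound areal density on the channel ceiling if every bubble in
#' the column below reaches the top surface (perfect stability, full
#' flotation): density = concentration x channel height.
#'
#' @param concentration Bulk concentration, particles/mL (>= 0).
#' @param channel_height Channel depth, m (> 0).
#' @return Surface density, particles/um^2.
#' @examples
#' predicted_surface_density(1e10, 0.4e-3)  # 4 per um^2
#' @export
predicted_surface_density <- function(concentration, channel_height) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (any(channel_height <= 0)) stop("channel_height must be > 0")
  # particles/mL * mL/um^3 (1e-12) * height in um
  concentration * 1e-12 * (channel_height * 1e6)
}

#' Fraction of bubbles of a given size reaching the top surface
#'
#' For bubbles initially uniformly distributed over the channel depth h,
#' the fraction of size-d bubbles that reach the ceiling within t is
#' min(1, rise_distance(d, t)/h). The population in contact with a cell
#' monolayer grown on the ceiling is therefore biased toward larger
#' bubbles.
#'
#' @inheritParams rise_distance
#' @param channel_height Channel depth, m (> 0).
#' @return Fraction in \[0, 1\], nondecreasing in both d and t.
#' @examples
#' flotation_transfer_fraction(458e-9, 3600, 400e-6)  # 1
#' flotation_transfer_fraction(324e-9, 3600, 400e-6)  # ~0.57
#' @export
flotation_transfer_fraction <- function(diameter, duration, channel_height,
                                        medium = medium_properties(),
                                        drag_constant = 18) {
  if (any(channel_height <= 0)) stop("channel_height must be > 0")
  pmin(1, rise_distance(diameter, duration, medium, drag_constant) /
         channel_height)
}
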