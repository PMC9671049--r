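# shared fixtures built in code

water <- function() medium_properties()  # mu = 8.9e-4, delta-rho = 990

# single-bin population pair at a given diameter (nm), for detection tests
single_bin_pair <- function(d_nm, bubbles_per_ml = 0, liposomes_per_ml = 0) {
  grid <- c(d_nm, d_nm + 10)
  mixed_population(
    size_distribution(grid, c(bubbles_per_ml, 0)),
    size_distribution(grid, c(liposomes_per_ml, 0)))
}

# dense Gaussian profile for peak-fit / TFI tests
gaussian_profile <- function(a = 1, xc = 8.5, sigma = 1, extent = 17,
                             dx = 0.01, offset = 0) {
  x <- seq(dx / 2, extent, by = dx)
  intensity_profile(x, a * exp(-(x - xc)^2 / (2 * sigma^2)) + offset)
}

# random well-formed size distribution for property tests
random_distribution <- function() {
  bins <- seq(50, 1000, 10)
  size_distribution(bins, stats::runif(length(bins))^2 * 1e8)
}
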