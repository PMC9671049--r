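# Seeded generators for every input the pipeline consumes, each
# returning its planted ground truth so round-trip tests never rely on
# hand-entered numbers.

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic-data generators
#'
#' One seeded parameter set driving all generators. Defaults emulate
#' the study conditions the analysis assumes: a ~300 nm-mode lognormal
#' bubble population at 1e10 /mL mixed with a 90 nm-mode liposome
#' population at 2.3e12 /mL (truncated at 150 nm — the precursor
#' contains no large vesicles), exponential concentration decay from
#' 1e9 /mL sampled every 5 min over 60 min with 5 percent
#' multiplicative noise, and tile scans of a 17 x 3.8 mm channel at
#' 20 um/px with disk-shaped cells and a Gaussian uptake stripe
#' centered mid-channel.
#'
#' @param seed Integer seed; fixes every generator's output
#'   bit-for-bit.
#' @param bubble_median_nm,bubble_sigma_ln,bubble_concentration
#'   Lognormal median (nm), log-SD, and total concentration (/mL) of
#'   the bubble subpopulation.
#' @param lip_mode_nm,lip_sigma_ln,lip_concentration,lip_max_nm Modal
#'   size (nm), log-SD, concentration (/mL) and hard upper truncation
#'   (nm) of the liposome subpopulation.
#' @param bin_centers_nm Diameter bin grid, nm.
#' @param decay_c0,decay_tau_half,decay_noise_frac,decay_times_min
#'   Initial concentration (/mL), half-life (min), multiplicative noise
#'   fraction, and sampling times (min) of decay series.
#' @param channel_length_mm,channel_width_mm,pixel_size_um Confocal map
#'   geometry.
#' @param cell_count,cell_radius_px Number and radius of synthetic
#'   cells (the tracer fills the whole cell disk).
#' @param stain_radius_px Radius of the bright live-stain core of each
#'   cell; smaller than `cell_radius_px`, mirroring real stains that
#'   binarize only the cell interior — the mask-building dilation step
#'   exists to recover the rest of the cell.
#' @param uptake_center_mm,uptake_sigma_mm,uptake_amplitude Planted
#'   Gaussian uptake stripe (amplitude 0 = control map).
#' @param green_cell,green_bg,red_bg,noise_sd Channel intensity levels
#'   and Gaussian noise SD, au.
#' @param ovb_count,ovb_radius_px,ovb_shape_px,ovb_pixel_size_um,
#'   ovb_bg,ovb_value,ovb_noise_sd Brightfield OVB image parameters.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1,
                           bubble_median_nm = 300, bubble_sigma_ln = 0.35,
                           bubble_concentration = 1e10,
                           lip_mode_nm = 90, lip_sigma_ln = 0.2,
                           lip_concentration = 2.3e12, lip_max_nm = 150,
                           bin_centers_nm = seq(50, 1000, by = 10),
                           decay_c0 = 1e9, decay_tau_half = 20,
                           decay_noise_frac = 0.05,
                           decay_times_min = seq(0, 60, by = 5),
                           channel_length_mm = 17, channel_width_mm = 3.8,
                           pixel_size_um = 20,
                           cell_count = 400, cell_radius_px = 6,
                           stain_radius_px = 3,
                           uptake_center_mm = 8.5, uptake_sigma_mm = 1.5,
                           uptake_amplitude = 50,
                           green_cell = 120, green_bg = 20, red_bg = 10,
                           noise_sd = 2,
                           ovb_count = 10, ovb_radius_px = 4,
                           ovb_shape_px = c(512, 512),
                           ovb_pixel_size_um = 0.5,
                           ovb_bg = 200, ovb_value = 50, ovb_noise_sd = 5) {
  if (seed != round(seed)) stop("seed must be an integer")
  spec <- as.list(environment())
  pos <- c("bubble_median_nm", "bubble_sigma_ln",
           "lip_mode_nm", "lip_sigma_ln", "lip_max_nm",
           "decay_c0", "decay_tau_half",
           "channel_length_mm", "channel_width_mm", "pixel_size_um",
           "cell_count", "cell_radius_px", "stain_radius_px",
           "uptake_sigma_mm",
           "ovb_radius_px", "ovb_pixel_size_um")
  for (nm in pos) if (any(spec[[nm]] <= 0)) stop(nm, " must be positive")
  if (uptake_center_mm < 0 || uptake_center_mm > channel_length_mm)
    stop("uptake_center_mm must lie inside the channel")
  if (stain_radius_px > cell_radius_px)
    stop("stain_radius_px cannot exceed cell_radius_px")
  structure(spec, class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("Generator spec (seed", x$seed, "): bubbles", x$bubble_median_nm,
      "nm median at", format(x$bubble_concentration, digits = 2),
      "/mL; decay tau1/2", x$decay_tau_half, "min; map",
      x$channel_length_mm, "x", x$channel_width_mm, "mm\n")
  invisible(x)
}

#' Synthetic lognormal size distribution
#'
#' Discretizes a lognormal number density on the spec's bin grid and
#' scales it to the requested total concentration (exactly). The
#' analytic ground truth of the planted lognormal — mode, mean and a
#' quantile function — is attached as attribute `"truth"`.
#'
#' @param spec A [generator_spec()].
#' @param median_nm,sigma_ln,concentration Override the spec's bubble
#'   parameters.
#' @param max_nm Hard upper truncation, nm (bins above it get zero and
#'   the rest are renormalized).
#' @param label Sample label.
#' @return A [size_distribution()].
#' @examples
#' d <- gen_size_distribution(generator_spec())
#' modal_size(d)
#' attr(d, "truth")$mode_nm
#' @export
gen_size_distribution <- function(spec = generator_spec(),
                                  median_nm = spec$bubble_median_nm,
                                  sigma_ln = spec$bubble_sigma_ln,
                                  concentration = spec$bubble_concentration,
                                  max_nm = Inf, label = "synthetic") {
  stopifnot(inherits(spec, "generator_spec"))
  bins <- spec$bin_centers_nm
  mu <- log(median_nm)
  dens <- stats::dlnorm(bins, meanlog = mu, sdlog = sigma_ln)
  dens[bins > max_nm] <- 0
  conc <- if (concentration > 0 && sum(dens) > 0)
    concentration * dens / sum(dens) else rep(0, length(bins))
  out <- size_distribution(bins, conc, label = label)
  attr(out, "truth") <- list(
    mode_nm = median_nm * exp(-sigma_ln^2),
    mean_nm = median_nm * exp(sigma_ln^2 / 2),
    quantile = function(p) stats::qlnorm(p, meanlog = mu, sdlog = sigma_ln),
    concentration = concentration)
  out
}

#' Synthetic mixed bubble/liposome population
#'
#' Bubble and liposome subpopulations on one grid, with gas (n = 1.00)
#' and liposome (n = 1.38) optics in water. The liposome lognormal is
#' parameterized by its mode (default 90 nm) and hard-truncated at
#' `lip_max_nm`.
#'
#' @param spec A [generator_spec()].
#' @return A [mixed_population()].
#' @export
gen_mixed_population <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  bub <- gen_size_distribution(spec, label = "bubbles")
  # lognormal mode = median * exp(-sigma^2); invert so the planted mode
  # lands exactly on the requested value
  lip_median <- spec$lip_mode_nm * exp(spec$lip_sigma_ln^2)
  lip <- gen_size_distribution(spec, median_nm = lip_median,
                               sigma_ln = spec$lip_sigma_ln,
                               concentration = spec$lip_concentration,
                               max_nm = spec$lip_max_nm,
                               label = "liposomes")
  mixed_population(bub, lip)
}

#' Synthetic exponential decay series
#'
#' C(t) = C0 exp(-t ln2 / tau) times lognormal multiplicative noise
#' (sdlog = `noise_frac`); the first point is noisy too, as in a real
#' measurement. Ground truth (C0, tau, per-point noiseless values) in
#' attribute `"truth"`.
#'
#' @param spec A [generator_spec()].
#' @param tau_half,c0,noise_frac,times_min Override the spec's decay
#'   parameters.
#' @param dilution_factor,label Passed to [decay_series()].
#' @return A [decay_series()].
#' @export
gen_decay_series <- function(spec = generator_spec(),
                             tau_half = spec$decay_tau_half,
                             c0 = spec$decay_c0,
                             noise_frac = spec$decay_noise_frac,
                             times_min = spec$decay_times_min,
                             dilution_factor = 1, label = "synthetic") {
  stopifnot(inherits(spec, "generator_spec"))
  if (tau_half <= 0) stop("tau_half must be > 0")
  clean <- c0 * exp(-times_min * log(2) / tau_half)
  noisy <- with_seed(spec$seed + 101L, {
    if (noise_frac > 0)
      clean * stats::rlnorm(length(clean), 0, noise_frac)
    else clean
  })
  out <- decay_series(times_min, noisy, dilution_factor, label)
  attr(out, "truth") <- list(c0 = c0, tau_half = tau_half,
                             rate_constant = log(2) / tau_half,
                             clean = clean)
  out
}

#' Synthetic two-channel confocal tile scan
#'
#' Green channel: disk-shaped cells at uniform random positions on a
#' dim background, plus Gaussian noise. Red channel: background plus,
#' inside cells only, a tracer intensity modulated along the chip by
#' A exp(-(x - xc)^2 / (2 sigma^2)), plus noise. Amplitude 0 gives a
#' control map. Attribute `"truth"` carries the planted profile
#' parameters and the analytic +/- 2 sigma integral of the planted
#' stripe (the quantity [quantify_uptake()] should recover).
#'
#' @param spec A [generator_spec()].
#' @param amplitude Override the planted uptake amplitude, au.
#' @return A [fluorescence_map()].
#' @export
gen_confocal_map <- function(spec = generator_spec(),
                             amplitude = spec$uptake_amplitude) {
  stopifnot(inherits(spec, "generator_spec"))
  ncols <- round(spec$channel_length_mm * 1000 / spec$pixel_size_um)
  nrows <- round(spec$channel_width_mm * 1000 / spec$pixel_size_um)
  draw_disks <- function(cy, cx, r) {
    img <- matrix(0L, nrows, ncols)
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    for (i in seq_along(cx)) {
      yy <- cy[i] + off$dy; xx <- cx[i] + off$dx
      keep <- yy >= 1 & yy <= nrows & xx >= 1 & xx <= ncols
      img[cbind(yy[keep], xx[keep])] <- 1L
    }
    img
  }
  with_seed(spec$seed + 202L, {
    cx <- sample.int(ncols, spec$cell_count, replace = TRUE)
    cy <- sample.int(nrows, spec$cell_count, replace = TRUE)
    cells <- draw_disks(cy, cx, spec$cell_radius_px)   # tracer support
    stain <- draw_disks(cy, cx, spec$stain_radius_px)  # bright stain core
    green <- spec$green_bg + (spec$green_cell - spec$green_bg) * stain +
      matrix(stats::rnorm(nrows * ncols, 0, spec$noise_sd), nrows, ncols)
    x_mm <- (seq_len(ncols) - 0.5) * spec$pixel_size_um / 1000
    stripe <- amplitude *
      exp(-(x_mm - spec$uptake_center_mm)^2 / (2 * spec$uptake_sigma_mm^2))
    red <- spec$red_bg + cells * matrix(stripe, nrows, ncols, byrow = TRUE) +
      matrix(stats::rnorm(nrows * ncols, 0, spec$noise_sd), nrows, ncols)
    map <- fluorescence_map(pmax(green, 0), pmax(red, 0),
                            spec$pixel_size_um, x_axis = "columns")
    capture <- stats::pnorm(2) - stats::pnorm(-2)
    attr(map, "truth") <- list(
      amplitude = amplitude,
      center_mm = spec$uptake_center_mm,
      sigma_mm = spec$uptake_sigma_mm,
      tfi_2sigma = amplitude * spec$uptake_sigma_mm * sqrt(2 * pi) * capture,
      cell_fraction = mean(cells))
    map
  })
}

#' Synthetic brightfield OVB images
#'
#' Dark disks (optically visible bubbles) on a bright noisy background,
#' placed without overlap by rejection sampling. Attribute `"truth"`
#' carries the true total count and the implied concentration.
#'
#' @param spec A [generator_spec()].
#' @param n_images Number of fields to generate.
#' @param chamber_depth_um Chamber depth used for the ground-truth
#'   concentration, um.
#' @return A list of intensity matrices.
#' @export
gen_brightfield_ovb <- function(spec = generator_spec(), n_images = 1,
                                chamber_depth_um = 50) {
  stopifnot(inherits(spec, "generator_spec"))
  nr <- spec$ovb_shape_px[1]; nc <- spec$ovb_shape_px[2]
  r <- spec$ovb_radius_px
  # sanity bound on packing: spots must plausibly fit without overlap
  if (spec$ovb_count * (2 * r)^2 > 0.25 * nr * nc)
    stop("cannot pack ", spec$ovb_count, " spots of radius ", r,
         " px into the frame without overlap")
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  with_seed(spec$seed + 303L, {
    imgs <- lapply(seq_len(n_images), function(im) {
      img <- spec$ovb_bg +
        matrix(stats::rnorm(nr * nc, 0, spec$ovb_noise_sd), nr, nc)
      placed <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(placed) < spec$ovb_count) {
        tries <- tries + 1L
        if (tries > 10000L) stop("impossible packing of OVB spots")
        y <- sample((r + 1):(nr - r), 1); x <- sample((r + 1):(nc - r), 1)
        if (nrow(placed) > 0 &&
            any((placed[, 1] - y)^2 + (placed[, 2] - x)^2 < (3 * r)^2))
          next
        placed <- rbind(placed, c(y, x))
        img[cbind(y + off$dy, x + off$dx)] <- spec$ovb_value
      }
      pmax(img, 0)
    })
    vol_um3 <- n_images * nr * nc * spec$ovb_pixel_size_um^2 *
      chamber_depth_um
    attr(imgs, "truth") <- list(
      count = n_images * spec$ovb_count,
      concentration_per_ml = n_images * spec$ovb_count / vol_um3 * 1e12)
    imgs
  })
}
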