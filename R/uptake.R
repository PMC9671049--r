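# Confocal fluorescence quantification pipeline: cell mask, background
# subtraction, masked axial profile, smoothing + baseline, Gaussian peak
# fit, and the integrated TFI uptake metric; plus brightfield counting
# of optically visible bubbles (OVBs).

#' Two-channel confocal tile-scan map
#'
#' Holds the live-stain (green) and tracer (red) channels of a tile
#' scan of the microfluidic channel, with pixel size metadata. The
#' chip's x-direction (along which uptake is profiled) is taken as the
#' image's long axis by default; images are stored with x along
#' columns.
#'
#' @param green,red Nonnegative intensity matrices of equal shape.
#' @param pixel_size_um Pixel size, um/px (isotropic).
#' @param x_axis `"long"` (default: chip x is the longer image axis),
#'   `"columns"`, or `"rows"`.
#' @return An object of class `fluorescence_map`.
#' @export
fluorescence_map <- function(green, red, pixel_size_um,
                             x_axis = c("long", "columns", "rows")) {
  x_axis <- match.arg(x_axis)
  stopifnot(is.matrix(green), is.matrix(red))
  if (!all(dim(green) == dim(red)))
    stop("green and red channels must have the same shape")
  if (any(green < 0) || any(red < 0)) stop("intensities must be >= 0")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  flip <- switch(x_axis,
                 columns = FALSE,
                 rows = TRUE,
                 long = nrow(green) > ncol(green))
  if (flip) { green <- t(green); red <- t(red) }
  structure(list(green = green, red = red, pixel_size_um = pixel_size_um),
            class = "fluorescence_map")
}

#' @export
print.fluorescence_map <- function(x, ...) {
  cat("Fluorescence map:", nrow(x$green), "x", ncol(x$green), "px at",
      x$pixel_size_um, "um/px (",
      round(ncol(x$green) * x$pixel_size_um / 1000, 2), "mm along chip )\n")
  invisible(x)
}

#' Binary cell mask from the live-stain channel
#'
#' Automatic (Otsu) binarization followed by morphological opening
#' (removes speckle noise smaller than the opening radius) and dilation
#' (grows the mask so whole cells, including dim rims, are included).
#' An all-constant image yields an empty mask with a warning.
#'
#' @param green Live-stain intensity matrix.
#' @param threshold Binarization threshold on the raw intensity scale;
#'   `NULL` (default) selects it by Otsu's method.
#' @param r_open,r_dil Disk radii (px) of the opening and dilation
#'   elements.
#' @return A 0/1 integer matrix of the same shape.
#' @export
make_cell_mask <- function(green, threshold = NULL, r_open = 2, r_dil = 3) {
  stopifnot(is.matrix(green))
  rng <- range(green)
  if (diff(rng) == 0) {
    warning("constant image: returning empty mask")
    return(matrix(0L, nrow(green), ncol(green)))
  }
  if (is.null(threshold)) {
    norm <- (green - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(norm))
  }
  bw <- EBImage::Image((green > threshold) * 1)
  if (r_open > 0)
    bw <- EBImage::opening(bw, EBImage::makeBrush(2 * r_open + 1, "disc"))
  if (r_dil > 0)
    bw <- EBImage::dilate(bw, EBImage::makeBrush(2 * r_dil + 1, "disc"))
  m <- EBImage::imageData(bw)
  storage.mode(m) <- "integer"
  m
}

#' Subtract a scalar background from the tracer channel
#'
#' The background is the median intensity of pixels outside the cell
#' mask (robust to uptake signal inside cells); the result is clipped
#' at zero. If the mask covers the whole image the 5th percentile of
#' the image is used instead, with a warning.
#'
#' @param red Tracer intensity matrix.
#' @param mask 0/1 cell mask of the same shape (e.g. from
#'   [make_cell_mask()]).
#' @return Background-subtracted matrix, clipped at 0; the estimated
#'   background is attached as attribute `"background"`.
#' @export
subtract_background <- function(red, mask) {
  stopifnot(is.matrix(red), is.matrix(mask))
  if (!all(dim(red) == dim(mask))) stop("red and mask shapes differ")
  outside <- red[mask == 0]
  if (length(outside) == 0L) {
    warning("mask covers entire image: background from 5th percentile")
    bg <- stats::quantile(red, 0.05, names = FALSE)
  } else {
    bg <- stats::median(outside)
  }
  out <- pmax(red - bg, 0)
  attr(out, "background") <- bg
  out
}

#' Intensity profile along the chip
#'
#' Uniformly sampled positions (mm) against mean intensity (au).
#'
#' @param x_mm Strictly increasing, uniformly spaced positions, mm.
#' @param intensity Intensities, au; same length.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(x_mm, intensity) {
  stopifnot(is.numeric(x_mm), is.numeric(intensity),
            length(x_mm) == length(intensity), length(x_mm) >= 2L)
  dx <- diff(x_mm)
  if (any(dx <= 0)) stop("x_mm must be strictly increasing")
  if (diff(range(dx)) > 1e-8 * mean(dx)) stop("x_mm must be uniformly spaced")
  structure(list(x_mm = as.numeric(x_mm), intensity = as.numeric(intensity)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("Intensity profile:", length(x$x_mm), "samples over",
      round(diff(range(x$x_mm)), 2), "mm\n")
  invisible(x)
}

#' Masked mean tracer profile along the chip
#'
#' Per-column mean of the (background-subtracted) tracer intensity over
#' cell-mask pixels only. Columns containing no mask pixels receive
#' linearly interpolated values and are flagged in the
#' `"interpolated_columns"` attribute.
#'
#' @param red_bgsub Background-subtracted tracer matrix (x along
#'   columns).
#' @param mask 0/1 cell mask of the same shape.
#' @param pixel_size_um Pixel size, um/px.
#' @return An [intensity_profile()] with x in mm from the left edge.
#' @export
masked_axial_profile <- function(red_bgsub, mask, pixel_size_um) {
  stopifnot(is.matrix(red_bgsub), is.matrix(mask))
  if (!all(dim(red_bgsub) == dim(mask))) stop("shapes differ")
  if (sum(mask) == 0) stop("empty mask: no cells to profile")
  npix <- colSums(mask)
  sums <- colSums(red_bgsub * mask)
  mean_i <- ifelse(npix > 0, sums / npix, NA_real_)
  x <- (seq_len(ncol(mask)) - 0.5) * pixel_size_um / 1000
  gaps <- which(is.na(mean_i))
  if (length(gaps) > 0)
    mean_i <- stats::approx(x[-gaps], mean_i[-gaps], xout = x,
                            rule = 2)$y
  p <- intensity_profile(x, mean_i)
  attr(p, "interpolated_columns") <- gaps
  p
}

# Whittaker-smoother baseline with iterative one-sided peak rejection:
# minimizes sum w_i (y_i - z_i)^2 + lambda sum (d2 z)^2; points more
# than clip_sigma robust-SDs ABOVE the current baseline are dropped
# (weight 0) and the fit repeated, so peaks are excluded while
# peak-free noise keeps a symmetric weight set (no systematic offset).
whittaker_baseline <- function(y, lambda, clip_sigma = 2.5, iterations = 10) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iterations)) {
    A <- Matrix::Diagonal(x = w) + P
    z <- as.numeric(Matrix::solve(A, w * y))
    r <- y - z
    s <- stats::mad(r[w > 0], center = 0)
    if (s == 0) break
    w_new <- as.numeric(r <= clip_sigma * s)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Smooth a profile and remove its slowly varying baseline
#'
#' Savitzky-Golay smoothing (polynomial order 2 over a `window_mm`-wide
#' odd sample window) followed by subtraction of a stiff
#' Whittaker-smoother baseline estimated with iterative one-sided peak
#' rejection, so that localized peaks survive while drifts and offsets
#' are removed. The baseline stiffness is set by `baseline_scale_mm`,
#' the length scale below which the baseline refuses to bend (it must
#' comfortably exceed the expected peak width).
#'
#' @param profile An [intensity_profile()].
#' @param window_mm Savitzky-Golay window, mm (default 2; must span at
#'   least 5 samples and be shorter than the profile).
#' @param poly_order Savitzky-Golay polynomial order.
#' @param baseline_scale_mm Baseline stiffness length scale, mm.
#' @param clip_sigma Peak-rejection threshold in robust noise SDs.
#' @return An [intensity_profile()] holding the smoothed,
#'   baseline-subtracted profile, with attributes `"baseline"` and
#'   `"smoothed"` (each a numeric vector on the same grid).
#' @export
smooth_and_baseline <- function(profile, window_mm = 2, poly_order = 2,
                                baseline_scale_mm = 7, clip_sigma = 2.5) {
  stopifnot(inherits(profile, "intensity_profile"))
  dx <- profile$x_mm[2] - profile$x_mm[1]
  extent <- diff(range(profile$x_mm))
  if (window_mm >= extent) stop("window_mm must be smaller than the profile")
  n_win <- max(5L, round(window_mm / dx))
  if (n_win %% 2L == 0L) n_win <- n_win + 1L
  if (n_win > length(profile$intensity))
    stop("profile too short for the smoothing window")
  sg <- signal::sgolayfilt(profile$intensity, p = poly_order, n = n_win)
  lambda <- (baseline_scale_mm / (2 * pi * dx))^4
  base <- whittaker_baseline(sg, lambda, clip_sigma)
  out <- intensity_profile(profile$x_mm, sg - base)
  attr(out, "baseline") <- base
  attr(out, "smoothed") <- sg
  out
}

#' Gaussian peak fit to a profile
#'
#' Nonlinear least-squares fit of A exp(-(x - xc)^2 / (2 sigma^2)) + c,
#' initialized from the profile maximum and its half-max width. The fit
#' is declared successful only if it converges with the center inside
#' the profile, sigma between `sigma_min_mm` and half the profile
#' extent, and amplitude exceeding 3x the noise scale (`noise_sd` if
#' supplied, otherwise the fit's residual SD) — otherwise downstream
#' integration falls back to a central fixed window.
#'
#' @param profile An [intensity_profile()] (>= 10 samples), typically
#'   the smoothed, baseline-subtracted profile.
#' @param noise_sd Optional robust noise scale of the underlying raw
#'   profile, au; used in the amplitude criterion.
#' @param sigma_min_mm Smallest credible peak sigma, mm.
#' @return An object of class `peak_fit`: `center_mm`, `sigma_mm`,
#'   `amplitude`, `offset`, `success`, `reason`.
#' @export
fit_gaussian_peak <- function(profile, noise_sd = NULL, sigma_min_mm = 0.1) {
  stopifnot(inherits(profile, "intensity_profile"))
  x <- profile$x_mm; y <- profile$intensity
  if (length(x) < 10L) stop("need >= 10 samples to fit a peak")
  extent <- diff(range(x))
  fail <- function(reason)
    structure(list(center_mm = NA_real_, sigma_mm = NA_real_,
                   amplitude = NA_real_, offset = NA_real_,
                   success = FALSE, reason = reason),
              class = "peak_fit")
  i_max <- which.max(y)
  c0 <- stats::median(y)
  a0 <- y[i_max] - c0
  if (a0 <= 0) return(fail("no positive excursion above the median"))
  half <- c0 + a0 / 2
  above <- which(y >= half)
  s0 <- max(diff(range(x[above])) / 2.355, 2 * (x[2] - x[1]))
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ A * exp(-(x - xc)^2 / (2 * s^2)) + c0f,
    start = list(A = a0, xc = x[i_max], s = s0, c0f = c0),
    control = minpack.lm::nls.lm.control(maxiter = 300))), silent = TRUE)
  if (inherits(fit, "try-error")) return(fail("fit did not converge"))
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); xc <- unname(cf["xc"])
  s <- abs(unname(cf["s"])); off <- unname(cf["c0f"])
  resid_sd <- stats::sd(stats::resid(fit))
  noise <- if (is.null(noise_sd)) resid_sd else noise_sd
  ok <- TRUE; reason <- "ok"
  if (xc < min(x) || xc > max(x)) { ok <- FALSE; reason <- "center outside profile" }
  else if (s < sigma_min_mm || s > extent / 2) { ok <- FALSE; reason <- "sigma outside credible range" }
  else if (!is.finite(A) || A <= 3 * noise) { ok <- FALSE; reason <- "amplitude below 3x noise" }
  structure(list(center_mm = xc, sigma_mm = s, amplitude = A, offset = off,
                 success = ok, reason = reason),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (x$success)
    cat(sprintf("Gaussian peak: xc = %.2f mm, sigma = %.2f mm, A = %.2f au\n",
                x$center_mm, x$sigma_mm, x$amplitude))
  else cat("Gaussian peak fit unsuccessful:", x$reason, "\n")
  invisible(x)
}

# trapezoidal integral of a profile over [lo, hi], with interpolated
# window endpoints
trapz_window <- function(profile, lo, hi) {
  x <- profile$x_mm; y <- profile$intensity
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, lo, rule = 2)$y, y[inside],
          stats::approx(x, y, hi, rule = 2)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Total fluorescence intensity over the uptake window
#'
#' Integrates the unsmoothed, background-subtracted profile over
#' the fitted peak's +/- 2 sigma window; if the peak fit was
#' unsuccessful (no clear uptake), over a fixed `fallback_window_mm`
#' window centered on the profile. Windows extending past the profile
#' are clipped with a warning.
#'
#' @param raw_profile An [intensity_profile()]: the non-smoothed,
#'   background-subtracted profile to integrate.
#' @param peak A `peak_fit` from [fit_gaussian_peak()].
#' @param fallback_window_mm Width of the central fallback window, mm.
#' @return An object of class `tfi_result`: `tfi` (au mm), `method`
#'   (`"gaussian-window"` or `"central-window"`), `peak`, `window`
#'   (c(lo, hi), mm).
#' @export
total_fluorescence_intensity <- function(raw_profile, peak,
                                         fallback_window_mm = 7) {
  stopifnot(inherits(raw_profile, "intensity_profile"),
            inherits(peak, "peak_fit"))
  rng <- range(raw_profile$x_mm)
  if (isTRUE(peak$success)) {
    lo <- peak$center_mm - 2 * peak$sigma_mm
    hi <- peak$center_mm + 2 * peak$sigma_mm
    method <- "gaussian-window"
  } else {
    mid <- mean(rng)
    lo <- mid - fallback_window_mm / 2
    hi <- mid + fallback_window_mm / 2
    method <- "central-window"
  }
  if (hi <= rng[1] || lo >= rng[2])
    stop("integration window lies entirely outside the profile")
  if (lo < rng[1] || hi > rng[2]) {
    warning("integration window clipped to profile bounds")
    lo <- max(lo, rng[1]); hi <- min(hi, rng[2])
  }
  structure(list(tfi = trapz_window(raw_profile, lo, hi),
                 method = method, peak = peak, window = c(lo, hi)),
            class = "tfi_result")
}

#' @export
print.tfi_result <- function(x, ...) {
  cat(sprintf("TFI = %.3f au mm (%s, window %.2f-%.2f mm)\n",
              x$tfi, x$method, x$window[1], x$window[2]))
  invisible(x)
}

#' Full uptake quantification pipeline
#'
#' Composes the pipeline stages: cell mask from the green channel,
#' scalar background subtraction on the red channel, masked axial
#' profile, Savitzky-Golay smoothing with baseline removal, Gaussian
#' peak fit, and window integration. The integrand is the unsmoothed
#' profile minus the estimated baseline. Deterministic given the map.
#'
#' @param map A [fluorescence_map()].
#' @param threshold,r_open,r_dil Passed to [make_cell_mask()].
#' @param window_mm,baseline_scale_mm Passed to [smooth_and_baseline()].
#' @param fallback_window_mm Passed to
#'   [total_fluorescence_intensity()].
#' @return A `tfi_result` with extra fields `raw_profile` (unsmoothed,
#'   baseline-removed), `smoothed_profile`, and `mask_fraction`.
#' @export
quantify_uptake <- function(map, threshold = NULL, r_open = 2, r_dil = 3,
                            window_mm = 2, baseline_scale_mm = 7,
                            fallback_window_mm = 7) {
  stopifnot(inherits(map, "fluorescence_map"))
  mask <- make_cell_mask(map$green, threshold, r_open, r_dil)
  red_bg <- subtract_background(map$red, mask)
  raw <- masked_axial_profile(red_bg, mask, map$pixel_size_um)
  sm <- smooth_and_baseline(raw, window_mm = window_mm,
                            baseline_scale_mm = baseline_scale_mm)
  noise_sd <- stats::mad(raw$intensity - attr(sm, "smoothed"))
  peak <- fit_gaussian_peak(sm, noise_sd = noise_sd)
  raw_based <- intensity_profile(raw$x_mm,
                                 raw$intensity - attr(sm, "baseline"))
  res <- total_fluorescence_intensity(raw_based, peak,
                                      fallback_window_mm = fallback_window_mm)
  res$raw_profile <- raw_based
  res$smoothed_profile <- sm
  res$mask_fraction <- mean(mask)
  res
}

#' Count optically visible bubbles in brightfield images
#'
#' Detects dark spots (OVBs appear as dark rings/discs on a bright
#' background) by robust thresholding — pixels more than
#' `threshold_sigma` robust SDs below the median — followed by
#' connected-component labelling with area bounds, and converts the
#' total count to a concentration using the imaged volume (field area x
#' chamber depth).
#'
#' @param images A list of intensity matrices (>= 1).
#' @param pixel_size_um Pixel size, um/px.
#' @param chamber_depth_um Counting-chamber depth, um (default 50).
#' @param threshold_sigma Detection threshold in robust SDs.
#' @param min_area_px,max_area_px Component area bounds, px.
#' @return Concentration, particles/mL, with attribute `"count"` (total
#'   spots over all images).
#' @export
count_ovb <- function(images, pixel_size_um, chamber_depth_um = 50,
                      threshold_sigma = 5, min_area_px = 4,
                      max_area_px = Inf) {
  if (!is.list(images) || length(images) == 0L)
    stop("supply a non-empty list of images")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  total <- 0L
  total_px <- 0
  for (img in images) {
    stopifnot(is.matrix(img))
    total_px <- total_px + length(img)
    bg <- stats::median(img)
    s <- stats::mad(img)
    bin <- img < bg - threshold_sigma * s
    if (!any(bin)) next
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    areas <- tabulate(as.integer(EBImage::imageData(lab)))
    total <- total + sum(areas >= min_area_px & areas <= max_area_px)
  }
  vol_um3 <- total_px * pixel_size_um^2 * chamber_depth_um
  conc <- total / vol_um3 * 1e12  # um^3 -> mL
  attr(conc, "count") <- total
  conc
}

#' Lower detection limit of brightfield bubble counting
#'
#' Concentration corresponding to one bubble in the total imaged
#' volume: 1 / (image area x chamber depth x number of images).
#'
#' @param image_area_um2 Area of one field of view, um^2.
#' @param n_images Number of fields.
#' @param chamber_depth_um Chamber depth, um.
#' @return Concentration, particles/mL.
#' @examples
#' ovb_detection_limit(2e4, 1, 50)  # 1e6 /mL
#' @export
ovb_detection_limit <- function(image_area_um2, n_images = 1,
                                chamber_depth_um = 50) {
  if (image_area_um2 <= 0 || n_images <= 0 || chamber_depth_um <= 0)
    stop("all inputs must be positive")
  1 / (image_area_um2 * chamber_depth_um * n_images) * 1e12
}
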