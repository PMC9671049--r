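# File-format adapters, configuration, and the report functions tying
# the stages into the three analyses (characterization, stability,
# uptake).

#' Read a size-distribution CSV
#'
#' Expected columns: `diameter_nm`, `concentration_per_ml`; comma
#' separated, '.' decimal, mandatory header, '#' comment lines. With
#' `tolerant = TRUE` the reader skips instrument preamble lines until
#' it finds a header whose fields match /diam/ and /conc/ (the common
#' NTA export layout).
#'
#' @param path CSV file path.
#' @param label Sample label; defaults to the file name.
#' @param tolerant Skip non-matching preamble lines before the header.
#' @return A [size_distribution()].
#' @export
read_size_distribution_csv <- function(path, label = basename(path),
                                       tolerant = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file (no data at row 1): ", path)
  header_at <- 1L
  if (tolerant) {
    hits <- vapply(lines, function(l) {
      f <- tolower(trimws(strsplit(l, ",")[[1]]))
      any(grepl("diam", f)) && any(grepl("conc", f))
    }, logical(1))
    if (!any(hits)) stop("no diameter/concentration header found in ", path)
    header_at <- which(hits)[1]
  }
  df <- utils::read.csv(text = paste(lines[header_at:length(lines)],
                                     collapse = "\n"),
                        check.names = FALSE)
  nm <- tolower(names(df))
  dcol <- which(grepl("diam", nm))[1]
  ccol <- which(grepl("conc", nm))[1]
  if (is.na(dcol) || is.na(ccol))
    stop("missing columns in ", path,
         ": need diameter_nm and concentration_per_ml (got: ",
         paste(names(df), collapse = ", "), ")")
  dv <- suppressWarnings(as.numeric(df[[dcol]]))
  cv <- suppressWarnings(as.numeric(df[[ccol]]))
  bad <- which(!is.finite(dv) | !is.finite(cv))
  if (length(bad) > 0)
    stop("non-numeric value at data row ", bad[1], " of ", path)
  size_distribution(dv, cv, label = label)
}

#' Write a size-distribution CSV
#' @param dist A [size_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(dist$label)) writeLines(paste("# label:", dist$label), con)
  writeLines("diameter_nm,concentration_per_ml", con)
  writeLines(paste(format(dist$bin_centers, digits = 15, trim = TRUE),
                   format(dist$number_concentration, digits = 15,
                          trim = TRUE), sep = ","), con)
  invisible(path)
}

#' Read a decay-series CSV
#'
#' Expected columns: `time_min`, `concentration_per_ml`; an optional
#' metadata comment `# dilution_factor: <x>` is honoured.
#'
#' @param path CSV file path.
#' @param label Sample label; defaults to the file name.
#' @return A [decay_series()].
#' @export
read_decay_csv <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  dil <- 1
  meta <- grep("^\\s*#\\s*dilution_factor\\s*:", lines, value = TRUE)
  if (length(meta) > 0)
    dil <- as.numeric(sub(".*:\\s*", "", meta[1]))
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file (no data at row 1): ", path)
  df <- utils::read.csv(text = paste(lines, collapse = "\n"))
  if (!all(c("time_min", "concentration_per_ml") %in% names(df)))
    stop("missing columns in ", path,
         ": need time_min and concentration_per_ml (got: ",
         paste(names(df), collapse = ", "), ")")
  decay_series(df$time_min, df$concentration_per_ml, dilution_factor = dil,
               label = label)
}

#' Write a decay-series CSV
#' @param series A [decay_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(series, path) {
  stopifnot(inherits(series, "decay_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# dilution_factor:", series$dilution_factor), con)
  writeLines("time_min,concentration_per_ml", con)
  writeLines(paste(format(series$times, digits = 15, trim = TRUE),
                   format(series$concentrations, digits = 15, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

# scale used when storing arbitrary-unit intensities as [0,1] floats
.tiff_scale <- 65535

#' Write / read a two-channel confocal map as multi-page TIFF
#'
#' Page 1 holds the green (live-stain) channel, page 2 the red
#' (tracer) channel, stored as 32-bit floats scaled by 1/65535; a YAML
#' sidecar (`<path>.yaml`) records the pixel size and scale. Round-trip
#' accuracy is limited by float32 (about 1e-7 relative).
#'
#' @param map A [fluorescence_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_confocal_tiff <- function(map, path) {
  stopifnot(inherits(map, "fluorescence_map"))
  tiff::writeTIFF(list(map$green / .tiff_scale, map$red / .tiff_scale),
                  path, bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size_um = map$pixel_size_um,
                        intensity_scale = .tiff_scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_confocal_tiff
#' @param pixel_size_um Pixel size; if `NULL`, read from the YAML
#'   sidecar.
#' @export
read_confocal_tiff <- function(path, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop("expected a 2-page TIFF (green, red); got ", length(pages),
         " page(s) in ", path)
  scale <- .tiff_scale
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(pixel_size_um))
    stop("pixel_size_um not given and no YAML sidecar found for ", path)
  fluorescence_map(pages[[1]] * scale, pages[[2]] * scale, pixel_size_um,
                   x_axis = "columns")
}

# ---- configuration ---------------------------------------------------------

#' Analysis configuration
#'
#' Nested list of every tunable constant, fully serializable to YAML.
#' Unknown keys in a loaded file are rejected (typos should fail, not
#' silently fall back to defaults).
#'
#' @return The default configuration (class `analysis_config`).
#' @export
analysis_config <- function() {
  structure(list(
    medium = list(viscosity_pa_s = 8.9e-4, density_kg_m3 = 998),
    gas = list(density_kg_m3 = 8),
    optics = list(wavelength_nm = 488, n_medium = 1.33, n_bubble = 1.00,
                  n_liposome = 1.38),
    transducer = list(center_frequency_mhz = 2.25, element_diameter_mm = 6.35,
                      sound_speed_m_s = 1480, standoff_mm = 20),
    flotation = list(duration_s = 3600, channel_height_mm = 0.4,
                     drag_constant = 18),
    detection = list(kappa = 5.1e15, threshold_au = 1),
    stability = list(log_domain = FALSE, free_lipid_stock_ug_ml = 40),
    imaging = list(r_open_px = 2, r_dil_px = 3, sg_window_mm = 2,
                   baseline_scale_mm = 7, fallback_window_mm = 7)
  ), class = "analysis_config")
}

check_config_keys <- function(x, ref, prefix = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra) > 0)
    stop("unknown config key(s): ",
         paste0(prefix, extra, collapse = ", "))
  for (nm in names(x))
    if (is.list(ref[[nm]]))
      check_config_keys(x[[nm]], ref[[nm]], paste0(prefix, nm, "."))
  invisible(TRUE)
}

#' Load an analysis configuration from YAML
#'
#' Values present in the file override the defaults of
#' [analysis_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  ref <- analysis_config()
  check_config_keys(user, ref)
  for (sec in names(user))
    for (key in names(user[[sec]]))
      ref[[sec]][[key]] <- user[[sec]][[key]]
  ref
}

#' Save an analysis configuration to YAML
#' @param config An `analysis_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_medium <- function(config)
  medium_properties(viscosity = config$medium$viscosity_pa_s,
                    medium_density = config$medium$density_kg_m3,
                    gas_density = config$gas$density_kg_m3)

# ---- report functions ------------------------------------------------------

#' Characterize size-distribution samples
#'
#' Per-sample summary of the statistics a characterization table
#' reports: modal size, mean size, 95th percentile, total
#' concentration, and gas volume fraction — optionally alongside the
#' same statistics after a predicted flotation period.
#'
#' @param samples A list of [size_distribution()] objects, or a
#'   character vector of CSV paths for [read_size_distribution_csv()].
#' @param config An `analysis_config`.
#' @param flotation Also report post-flotation (top-of-channel)
#'   statistics using the config's flotation duration and channel
#'   height.
#' @return A data.frame, one row per sample.
#' @export
characterize_samples <- function(samples, config = analysis_config(),
                                 flotation = FALSE) {
  if (is.character(samples))
    samples <- lapply(samples, read_size_distribution_csv)
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "size_distribution")))
  rows <- lapply(samples, function(d) {
    row <- data.frame(
      label = d$label,
      modal_size_nm = modal_size(d),
      mean_size_nm = mean_size(d),
      d95_nm = percentile_size(d, 95),
      total_concentration_per_ml = total_concentration(d),
      gas_volume_fraction_pct = gas_volume_fraction(d))
    if (flotation) {
      shifted <- apply_flotation(
        d, config$flotation$duration_s,
        config$flotation$channel_height_mm * 1e-3,
        config_medium(config), config$flotation$drag_constant)
      row$modal_size_post_flotation_nm <- modal_size(shifted)
      row$surface_density_per_um2 <- predicted_surface_density(
        total_concentration(d), config$flotation$channel_height_mm * 1e-3)
    }
    row
  })
  do.call(rbind, rows)
}

#' Fit and summarize decay series
#'
#' Fits each series with [fit_exponential_decay()] and reports
#' half-life with standard error, fit quality, 60 min retention
#' (dilution-adjusted, from the fitted curve), and the free-lipid
#' concentration implied by the series' dilution factor. Non-decaying
#' series are flagged, not fatal.
#'
#' @param series_list A list of [decay_series()] objects or a character
#'   vector of CSV paths.
#' @param config An `analysis_config`.
#' @param json_path Optional path; when given, the report rows are also
#'   written as JSON records.
#' @return A data.frame, one row per series.
#' @export
stability_report <- function(series_list, config = analysis_config(),
                             json_path = NULL) {
  if (is.character(series_list))
    series_list <- lapply(series_list, read_decay_csv)
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, logical(1), "decay_series")))
  rows <- lapply(series_list, function(s) {
    fit <- withCallingHandlers(
      fit_exponential_decay(s, log_domain = config$stability$log_domain),
      warning = function(w) invokeRestart("muffleWarning"))
    t_end <- max(s$times)
    retention <- if (fit$status == "ok")
      100 * exp(-fit$rate_constant * t_end) else 100
    data.frame(label = s$label,
               tau_half_min = fit$half_life,
               tau_half_se_min = fit$se[["half_life"]],
               r_squared = fit$r_squared,
               status = fit$status,
               retention_60min_pct = retention,
               dilution_factor = s$dilution_factor,
               free_lipid_ug_ml = free_lipid_concentration(
                 s$dilution_factor, config$stability$free_lipid_stock_ug_ml))
  })
  out <- do.call(rbind, rows)
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  out
}

#' Quantify uptake across confocal maps
#'
#' Runs [quantify_uptake()] on each map and tabulates the TFI metric,
#' integration method and window, and fitted peak parameters; profile
#' CSVs (x_mm, intensity_au) can be written alongside.
#'
#' @param maps A list of [fluorescence_map()] objects or a character
#'   vector of 2-page TIFF paths.
#' @param config An `analysis_config`.
#' @param profile_dir Optional directory for per-map profile CSVs.
#' @return A data.frame, one row per map.
#' @export
uptake_report <- function(maps, config = analysis_config(),
                          profile_dir = NULL) {
  if (is.character(maps)) {
    paths <- maps
    maps <- lapply(paths, read_confocal_tiff)
    names(maps) <- basename(paths)
  }
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "fluorescence_map")))
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    names(maps) <- paste0("map", seq_along(maps))
  img <- config$imaging
  rows <- lapply(names(maps), function(nm) {
    res <- quantify_uptake(maps[[nm]], r_open = img$r_open_px,
                           r_dil = img$r_dil_px,
                           window_mm = img$sg_window_mm,
                           baseline_scale_mm = img$baseline_scale_mm,
                           fallback_window_mm = img$fallback_window_mm)
    if (!is.null(profile_dir)) {
      dir.create(profile_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(
        data.frame(x_mm = res$raw_profile$x_mm,
                   intensity_au = res$raw_profile$intensity),
        file.path(profile_dir, paste0(nm, "_profile.csv")),
        row.names = FALSE)
    }
    data.frame(label = nm,
               tfi_au_mm = res$tfi,
               method = res$method,
               x_c_mm = res$peak$center_mm,
               sigma_mm = res$peak$sigma_mm,
               window_lo_mm = res$window[1],
               window_hi_mm = res$window[2],
               mask_fraction = res$mask_fraction)
  })
  do.call(rbind, rows)
}
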