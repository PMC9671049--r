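# Decay-curve fitting, half-life estimation, and the dilution /
# free-lipid / interbubble-spacing stability analysis.

#' Concentration decay time series
#'
#' Concentration-vs-time measurements of a bubble sample, as produced by
#' repeated NTA acquisitions over a storage period.
#'
#' @param times Measurement times, min; strictly increasing, starting
#'   at 0; length >= 3.
#' @param concentrations Positive concentrations, particles/mL.
#' @param dilution_factor Dilution applied before measurement (>= 1).
#' @param label Sample label.
#' @return An object of class `decay_series`.
#' @examples
#' decay_series(seq(0, 60, 5), 1e9 * exp(-seq(0, 60, 5) * log(2) / 20))
#' @export
decay_series <- function(times, concentrations, dilution_factor = 1,
                         label = "") {
  stopifnot(is.numeric(times), is.numeric(concentrations))
  if (length(times) != length(concentrations) || length(times) < 3L)
    stop("times and concentrations must have equal length >= 3")
  if (times[1] != 0) stop("times must start at 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 dilution_factor = dilution_factor,
                 label = as.character(label)),
            class = "decay_series")
}

#' @export
print.decay_series <- function(x, ...) {
  cat("Decay series", if (nzchar(x$label)) paste0("'", x$label, "'"), ":",
      length(x$times), "points over", max(x$times), "min, C0 =",
      format(x$concentrations[1], digits = 3), "/mL, dilution",
      x$dilution_factor, "\n")
  invisible(x)
}

#' Fit a single-exponential decay to a concentration series
#'
#' Least-squares fit of C(t) = C0 exp(-k t) — no offset term, so the
#' half-life tau = ln(2)/k is well defined on short observation
#' windows. By default the fit is unweighted on the raw concentrations
#' (Levenberg-Marquardt, started from the log-linear regression); with
#' `log_domain = TRUE` the log-linear regression itself is the fit,
#' which is the maximum-likelihood choice under multiplicative
#' (lognormal) noise.
#'
#' A series whose best-fit rate constant is not positive is flagged
#' (`status = "non-decaying"`) and reported with infinite half-life
#' rather than an error.
#'
#' @param series A [decay_series()].
#' @param log_domain Fit ln C linearly instead of C nonlinearly.
#' @return An object of class `stability_fit`: fields
#'   `initial_concentration`, `rate_constant` (1/min), `half_life`
#'   (min), `se` (named standard errors, with `half_life` propagated by
#'   the delta method), `r_squared`, `status` ("ok" or "non-decaying"),
#'   `label`.
#' @examples
#' t <- seq(0, 60, 5)
#' fit_exponential_decay(decay_series(t, 100 * exp(-t * log(2) / 20)))
#' @export
fit_exponential_decay <- function(series, log_domain = FALSE) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$times
  y <- series$concentrations
  # log-linear regression: start values and the log-domain fit itself
  lf <- stats::lm(log(y) ~ t)
  k0 <- -unname(stats::coef(lf)[2])
  c0 <- exp(unname(stats::coef(lf)[1]))

  if (log_domain) {
    k <- k0; c0_hat <- c0
    # suppressed: summary.lm warns about "essentially perfect" fits on
    # noiseless input, a legitimate case here
    sm <- suppressWarnings(summary(lf))$coefficients
    se_k <- sm[2, 2]
    se_c0 <- c0 * sm[1, 2]
    fitted <- c0_hat * exp(-k * t)
  } else {
    fit <- try(minpack.lm::nlsLM(
      y ~ C0 * exp(-k * t),
      start = list(C0 = c0, k = max(k0, 1e-8)),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      k <- k0; c0_hat <- c0
      se_k <- NA_real_; se_c0 <- NA_real_
      fitted <- c0_hat * exp(-k * t)
    } else {
      cf <- stats::coef(fit)
      k <- unname(cf["k"]); c0_hat <- unname(cf["C0"])
      sm <- summary(fit)$coefficients
      se_c0 <- sm["C0", "Std. Error"]; se_k <- sm["k", "Std. Error"]
      fitted <- stats::fitted(fit)
    }
  }

  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  # non-decaying: negative rate, or decay over the whole observation
  # window indistinguishable from none
  if (!is.finite(k) || k <= 0 || k * max(t) < 1e-6) {
    warning("series is not decaying: half-life reported as infinite")
    return(structure(list(initial_concentration = c0_hat, rate_constant = k,
                          half_life = Inf,
                          se = c(initial_concentration = se_c0,
                                 rate_constant = se_k, half_life = NA_real_),
                          r_squared = r2, status = "non-decaying",
                          label = series$label),
                     class = "stability_fit"))
  }
  structure(list(initial_concentration = c0_hat, rate_constant = k,
                 half_life = log(2) / k,
                 se = c(initial_concentration = se_c0, rate_constant = se_k,
                        half_life = log(2) / k^2 * se_k),  # delta method
                 r_squared = r2, status = "ok", label = series$label),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("Exponential decay fit%s: tau1/2 = %.2f +/- %.2f min (k = %.4g /min, R2 = %.3f)\n",
                if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
                x$half_life, x$se[["half_life"]], x$rate_constant,
                x$r_squared))
  else
    cat("Non-decaying series: half-life infinite\n")
  invisible(x)
}

#' Dilution-adjusted retention percentage
#'
#' Final concentration corrected for the measurement dilution and
#' normalized to the initial concentration, in percent: an unchanged
#' sample gives 100.
#'
#' @param initial Initial concentration, particles/mL (> 0).
#' @param final Final measured concentration, particles/mL.
#' @param dilution_factor Dilution applied before the final measurement
#'   (>= 1).
#' @return Retention, percent.
#' @examples
#' normalized_retention(1e9, 5e8)        # 50
#' normalized_retention(1e9, 1e8, 10)    # 100
#' @export
normalized_retention <- function(initial, final, dilution_factor = 1) {
  if (any(initial <= 0)) stop("initial concentration must be > 0")
  if (any(final < 0)) stop("final concentration must be >= 0")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  100 * final * dilution_factor / initial
}

#' Free lipid concentration after dilution
#'
#' The non-shell ("free") lipid co-diluted with the sample, from an
#' assumed stock free-lipid concentration in the undiluted sample
#' (default 40 ug/mL).
#'
#' @param dilution_factor Dilution applied (>= 1).
#' @param stock Free lipid concentration of the undiluted sample, ug/mL.
#' @return Concentration, ug/mL.
#' @examples
#' free_lipid_concentration(1)   # 40
#' free_lipid_concentration(50)  # 0.8
#' @export
free_lipid_concentration <- function(dilution_factor, stock = 40) {
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (stock <= 0) stop("stock must be > 0")
  stock / dilution_factor
}

#' Fit retention against interbubble spacing
#'
#' Fits retention = A exp(-(l/d)/B) to retention percentages measured
#' at different l/d ratios (spacing over mean diameter), the model used
#' to extrapolate concentration-dependent stability beyond the measured
#' range.
#'
#' @param l_over_d_values Dimensionless l/d values (> 0), length >= 3,
#'   spanning more than 1 unit.
#' @param retention_values Retention percentages (>= 0), same length.
#' @return An object of class `spacing_stability_curve` with fields
#'   `amplitude` (A, percent), `decay_scale` (B, dimensionless), `se`,
#'   `r_squared`, `status`, plus the input points.
#' @examples
#' x <- c(2, 5, 10, 20, 30)
#' fit_spacing_stability(x, 120 * exp(-x / 20))
#' @export
fit_spacing_stability <- function(l_over_d_values, retention_values) {
  stopifnot(is.numeric(l_over_d_values), is.numeric(retention_values))
  if (length(l_over_d_values) != length(retention_values) ||
      length(l_over_d_values) < 3L)
    stop("need >= 3 (l/d, retention) points of equal length")
  if (any(l_over_d_values <= 0)) stop("l/d values must be > 0")
  if (any(retention_values < 0)) stop("retention values must be >= 0")
  if (diff(range(l_over_d_values)) <= 1)
    stop("l/d values must span more than 1 unit")
  x <- l_over_d_values; y <- retention_values
  pos <- y > 0
  lf <- stats::lm(log(y[pos]) ~ x[pos])
  b0 <- -1 / unname(stats::coef(lf)[2])
  a0 <- exp(unname(stats::coef(lf)[1]))
  if (!is.finite(b0) || b0 <= 0) {
    warning("retention does not decay with l/d: fit flagged")
    return(structure(list(amplitude = a0, decay_scale = Inf,
                          se = c(amplitude = NA_real_, decay_scale = NA_real_),
                          r_squared = NA_real_, status = "non-decaying",
                          l_over_d_values = x, retention_values = y),
                     class = "spacing_stability_curve"))
  }
  fit <- minpack.lm::nlsLM(y ~ A * exp(-x / B),
                           start = list(A = a0, B = b0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(amplitude = unname(cf["A"]), decay_scale = unname(cf["B"]),
                 se = c(amplitude = sm["A", "Std. Error"],
                        decay_scale = sm["B", "Std. Error"]),
                 r_squared = r2, status = "ok",
                 l_over_d_values = x, retention_values = y),
            class = "spacing_stability_curve")
}

#' @export
print.spacing_stability_curve <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Spacing-stability fit: retention = %.1f exp(-(l/d)/%.2f), R2 = %.3f\n",
                x$amplitude, x$decay_scale, x$r_squared))
    if (x$amplitude > 100)
      cat(sprintf("  crosses 100%% retention at l/d = %.2f\n",
                  required_spacing_for_full_stability(x)))
  } else cat("Spacing-stability fit: non-decaying (flagged)\n")
  invisible(x)
}

#' l/d at which the fitted retention curve reaches 100 percent
#'
#' Solves A exp(-x/B) = 100 for x = B ln(A/100): the interbubble
#' spacing ratio at which a sample would be predicted fully stable over
#' the observation window. Requires the fitted amplitude to exceed 100
#' (otherwise the curve never crosses and extrapolation is impossible).
#'
#' @param fit A `spacing_stability_curve` from [fit_spacing_stability()].
#' @return Dimensionless l/d.
#' @examples
#' x <- c(2, 5, 10, 20, 30)
#' f <- fit_spacing_stability(x, 200 * exp(-x / 10))
#' required_spacing_for_full_stability(f)  # 10*ln(2)
#' @export
required_spacing_for_full_stability <- function(fit) {
  stopifnot(inherits(fit, "spacing_stability_curve"))
  if (fit$status != "ok") stop("fit is flagged non-decaying")
  if (fit$amplitude <= 100)
    stop("fitted amplitude <= 100%: curve never crosses full retention")
  fit$decay_scale * log(fit$amplitude / 100)
}
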