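#' Exponential apodization
#'
#' Multiplies the FID by `exp(-pi * lb * t)`, the exponential weighting that
#' adds `lb` Hz to every Lorentzian linewidth while leaving peak areas
#' unchanged. The default processing chain uses 0.3 Hz.
#'
#' @param fid an `ars_fid`.
#' @param line_broadening line broadening in Hz (>= 0; 0 is the identity).
#' @return the apodized `ars_fid`.
#' @export
apodize <- function(fid, line_broadening = fid$params$line_broadening_default) {
  if (line_broadening < 0)
    stop("invalid_line_broadening: line_broadening must be >= 0")
  n <- length(fid$data)
  t <- (seq_len(n) - 1) / fid$params$sweep_width
  fid$data <- fid$data * exp(-pi * line_broadening * t)
  fid$processing_log <- c(fid$processing_log,
                          sprintf("apodize(lb=%g Hz)", line_broadening))
  fid
}

#' Zero filling
#'
#' Appends zeros to the FID, multiplying the number of complex points by
#' `factor` (a power of two). Interpolates the spectrum without changing
#' peak areas or linewidths.
#'
#' @param fid an `ars_fid`.
#' @param factor integer power-of-two multiplier (>= 1; 1 is the identity).
#' @return the zero-filled `ars_fid`.
#' @export
zero_fill <- function(fid, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 1 || bitwAnd(factor, factor - 1L) != 0L)
    stop("invalid_zero_fill: factor must be a power-of-two integer >= 1")
  if (factor > 1L) {
    n <- length(fid$data)
    fid$data <- c(fid$data, complex(real = numeric(n * (factor - 1L)),
                                    imaginary = numeric(n * (factor - 1L))))
  }
  fid$processing_log <- c(fid$processing_log,
                          sprintf("zero_fill(factor=%d)", factor))
  fid
}

#' Fourier transform to a calibrated-frequency spectrum
#'
#' Discrete Fourier transform of the FID, scaled by the dwell time so that
#' window integrals approximate the continuous-transform Lorentzian areas.
#' The first time-domain point is halved (trapezoid end correction) to
#' avoid a constant baseline offset. The frequency axis is mapped to ppm
#' with the carrier (mid-sweep) frequency at `params$ref_ppm`, stored in
#' descending ppm order.
#'
#' @param fid an `ars_fid` (non-empty, finite).
#' @return an `ars_spectrum` with fields `real`, `imag`, `ppm`, `params`,
#'   `processing_log`.
#' @export
fourier_transform <- function(fid) {
  n <- length(fid$data)
  if (n == 0) stop("empty_fid: cannot transform an empty FID")
  x <- fid$data
  x[1] <- x[1] / 2
  dt <- 1 / fid$params$sweep_width
  s <- stats::fft(x) * dt
  # reorder so frequency runs from -sw/2 to +sw/2 - df
  ord <- c((n %/% 2 + 1):n, 1:(n %/% 2))
  f <- ((seq_len(n) - 1) - n %/% 2) * fid$params$sweep_width / n
  ppm_asc <- fid$params$ref_ppm + f / fid$params$spectrometer_freq
  s <- s[ord]
  idx <- rev(seq_len(n))   # descending ppm, display convention
  structure(list(real = Re(s)[idx], imag = Im(s)[idx], ppm = ppm_asc[idx],
                 params = fid$params,
                 processing_log = c(fid$processing_log, "fourier_transform()")),
            class = "ars_spectrum")
}

#' @export
print.ars_spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d points, %.2f to %.2f ppm\nprocessing: %s\n",
              length(x$real), x$ppm[1], x$ppm[length(x$ppm)],
              paste(x$processing_log, collapse = " -> ")))
  invisible(x)
}

#' Phase-correction parameters
#'
#' @param zero_order zero-order phase in degrees, in (-180, 180].
#' @param first_order first-order phase in degrees across the full sweep.
#' @param pivot pivot chemical shift in ppm for the first-order term.
#' @return an object of class `ars_phase`.
#' @export
phase_params <- function(zero_order = 0, first_order = 0, pivot = 6.5) {
  if (zero_order <= -180 || zero_order > 180)
    stop("invalid_phase: zero_order must lie in (-180, 180]")
  structure(list(zero_order = zero_order, first_order = first_order,
                 pivot = pivot), class = "ars_phase")
}

apply_phase_angles <- function(spectrum, zero_order, first_order, pivot) {
  span <- abs(spectrum$ppm[1] - spectrum$ppm[length(spectrum$ppm)])
  phi <- (zero_order + first_order * (spectrum$ppm - pivot) / span) * pi / 180
  z <- complex(real = spectrum$real, imaginary = spectrum$imag) * exp(1i * phi)
  spectrum$real <- Re(z)
  spectrum$imag <- Im(z)
  spectrum
}

phase_objective <- function(re) {
  m <- max(abs(re))
  if (m == 0) return(0)
  reN <- re / m
  neg <- sum(pmin(reN, 0)^2)
  h <- abs(diff(reN))
  tot <- sum(h)
  if (tot > 0) {
    h <- h / tot
    h <- h[h > 0]
    ent <- -sum(h * log(h))
  } else ent <- 0
  neg + 1e-4 * ent
}

#' Phase correction
#'
#' Applies zero- and first-order phase correction. With explicit
#' [phase_params()] the given angles are applied exactly (manual mode).
#' With `"auto"`, the angles minimizing a negativity-plus-entropy objective
#' on the real trace are found by a 5-degree zero-order grid search
#' followed by Nelder-Mead refinement over both orders; if the optimizer
#' fails to converge the best candidate is still applied and the failure is
#' flagged in the processing log.
#'
#' @param spectrum an `ars_spectrum`.
#' @param params an `ars_phase` or the string `"auto"`.
#' @return the phased `ars_spectrum`.
#' @export
phase <- function(spectrum, params = "auto") {
  if (inherits(params, "ars_phase")) {
    out <- apply_phase_angles(spectrum, params$zero_order, params$first_order,
                              params$pivot)
    out$processing_log <- c(out$processing_log,
                            sprintf("phase(manual, zero=%g, first=%g, pivot=%g)",
                                    params$zero_order, params$first_order,
                                    params$pivot))
    return(out)
  }
  if (!identical(params, "auto"))
    stop("invalid_phase: params must be an ars_phase object or \"auto\"")
  pivot <- spectrum$params$ref_ppm
  # coarse zero-order grid on a decimated trace
  dec <- seq(1, length(spectrum$real), by = 4L)
  zdec <- complex(real = spectrum$real[dec], imaginary = spectrum$imag[dec])
  grid <- seq(-175, 180, by = 5)
  obj0 <- vapply(grid, function(p0)
    phase_objective(Re(zdec * exp(1i * p0 * pi / 180))), numeric(1))
  p0 <- grid[which.min(obj0)]
  fit <- optim(c(p0, 0), function(par) {
    phase_objective(apply_phase_angles(spectrum, par[1], par[2], pivot)$real)
  }, method = "Nelder-Mead", control = list(maxit = 400, reltol = 1e-10))
  zo <- ((fit$par[1] + 180) %% 360) - 180
  if (zo == -180) zo <- 180
  out <- apply_phase_angles(spectrum, fit$par[1], fit$par[2], pivot)
  flag <- if (fit$convergence == 0) "" else ", NOT_CONVERGED"
  out$processing_log <- c(out$processing_log,
                          sprintf("phase(auto, zero=%.3f, first=%.3f, pivot=%g%s)",
                                  zo, fit$par[2], pivot, flag))
  attr(out, "phase_fit") <- list(zero_order = zo, first_order = fit$par[2],
                                 converged = fit$convergence == 0)
  out
}

# signal-free windows spread across the sweep: polynomial baselines fitted
# on edge-only anchors are ill-conditioned mid-spectrum and amplify noise
# severalfold at the analyte windows, so anchors bracket them instead
default_anchor_regions <- function() {
  list(c(12.5, 11.5), c(9.3, 8.3), c(7.5, 6.6), c(2.0, 0.5))
}

default_noise_region <- function() c(11.4, 10.4)

windows_overlap <- function(a, b) {
  # windows are (high_ppm, low_ppm)
  min(a[1], b[1]) > max(a[2], b[2])
}

ppm_index <- function(spectrum, window) {
  which(spectrum$ppm <= window[1] & spectrum$ppm >= window[2])
}

#' Baseline correction
#'
#' Fits a polynomial (default cubic) to signal-free anchor regions of the
#' real trace and subtracts it across the whole spectrum. Anchor regions
#' must not overlap the integration windows passed in `avoid`.
#'
#' @param spectrum a phased `ars_spectrum`.
#' @param method `"poly"` (polynomial on anchors).
#' @param degree polynomial degree (0 = constant offset).
#' @param anchors list of `(high_ppm, low_ppm)` signal-free windows.
#' @param avoid list of `(high_ppm, low_ppm)` windows (typically the
#'   integration windows) that anchors must not touch.
#' @return the corrected `ars_spectrum`.
#' @export
baseline_correct <- function(spectrum, method = "poly", degree = 3,
                             anchors = default_anchor_regions(),
                             avoid = list(c(6.10, 5.90), c(9.89, 9.69))) {
  if (!identical(method, "poly"))
    stop("invalid_baseline_method: only \"poly\" is implemented")
  for (a in anchors) for (w in avoid) {
    if (windows_overlap(a, w))
      stop(sprintf("anchor_overlaps_integration_window: anchor (%.2f, %.2f) vs window (%.2f, %.2f)",
                   a[1], a[2], w[1], w[2]))
  }
  idx <- sort(unique(unlist(lapply(anchors, ppm_index, spectrum = spectrum))))
  if (length(idx) < degree + 1)
    stop("invalid_anchors: not enough anchor points for the requested degree")
  x <- spectrum$ppm[idx]
  y <- spectrum$real[idx]
  if (degree == 0) {
    base <- rep(mean(y), length(spectrum$ppm))
  } else {
    fit <- lm(y ~ poly(x, degree, raw = TRUE))
    base <- as.numeric(cbind(1, stats::poly(spectrum$ppm, degree, raw = TRUE)) %*%
                         stats::coef(fit))
  }
  spectrum$real <- spectrum$real - base
  spectrum$processing_log <- c(spectrum$processing_log,
                               sprintf("baseline_correct(poly, degree=%d)", degree))
  spectrum
}

#' RMS noise of a signal-free region
#'
#' @param spectrum an `ars_spectrum`.
#' @param window `(high_ppm, low_ppm)` signal-free region.
#' @return standard deviation of the real trace in the window.
#' @export
spectrum_noise_rms <- function(spectrum, window = default_noise_region()) {
  idx <- ppm_index(spectrum, window)
  if (length(idx) < 2) stop("invalid_noise_window: window contains too few points")
  sd(spectrum$real[idx])
}

#' Chemical-shift calibration
#'
#' Shifts the ppm axis so that the tallest peak inside the search window
#' sits exactly at `reference_shift`. The default reference is the residual
#' DMSO solvent line at 2.50 ppm. A peak is required to rise at least five
#' times above the noise RMS.
#'
#' @param spectrum an `ars_spectrum`.
#' @param reference_shift target chemical shift in ppm.
#' @param window `(high_ppm, low_ppm)` search window.
#' @param noise_window signal-free region used to estimate the noise RMS.
#' @return the re-referenced `ars_spectrum`.
#' @export
calibrate_ppm <- function(spectrum, reference_shift = 2.50,
                          window = c(2.70, 2.30),
                          noise_window = default_noise_region()) {
  idx <- ppm_index(spectrum, window)
  if (length(idx) == 0) stop("no_reference_peak: empty search window")
  rms <- spectrum_noise_rms(spectrum, noise_window)
  # a usable reference must both clear the noise and be a major line
  thresh <- max(5 * rms, 1e-3 * max(abs(spectrum$real)))
  peak <- idx[which.max(spectrum$real[idx])]
  if (spectrum$real[peak] <= thresh)
    stop(sprintf("no_reference_peak: no peak above 5x noise RMS in (%.2f, %.2f) ppm",
                 window[1], window[2]))
  delta <- reference_shift - spectrum$ppm[peak]
  spectrum$ppm <- spectrum$ppm + delta
  spectrum$processing_log <- c(spectrum$processing_log,
                               sprintf("calibrate_ppm(ref=%g, shift=%+.5f)",
                                       reference_shift, delta))
  spectrum
}

#' Full processing chain
#'
#' Runs the standard chain: exponential apodization (0.3 Hz), zero filling
#' (factor 2), Fourier transform, phase correction (automatic by default,
#' manual with explicit [phase_params()]), polynomial baseline correction
#' and chemical-shift calibration on the residual DMSO line.
#'
#' @param fid an `ars_fid`.
#' @param line_broadening Hz of exponential apodization.
#' @param zero_fill_factor power-of-two zero-filling multiplier.
#' @param phase_with `"auto"`, an `ars_phase`, or `"none"` to skip.
#' @param baseline_degree polynomial degree for the baseline (NULL skips).
#' @param calibrate calibrate the ppm axis on the DMSO line?
#' @return a processed `ars_spectrum`.
#' @export
process_fid <- function(fid,
                        line_broadening = fid$params$line_broadening_default,
                        zero_fill_factor = 2L,
                        phase_with = "auto",
                        baseline_degree = 3,
                        calibrate = TRUE) {
  fid <- apodize(fid, line_broadening)
  fid <- zero_fill(fid, zero_fill_factor)
  spec <- fourier_transform(fid)
  if (!identical(phase_with, "none")) spec <- phase(spec, phase_with)
  if (!is.null(baseline_degree)) spec <- baseline_correct(spec, degree = baseline_degree)
  if (calibrate) spec <- calibrate_ppm(spec)
  spec
}

#' Window integral of the real trace
#'
#' Trapezoidal integral of the real trace over a `(high_ppm, low_ppm)`
#' window, in amplitude x Hz units (so it is comparable across digital
#' resolutions and to analytic Lorentzian areas).
#'
#' @param spectrum an `ars_spectrum`.
#' @param window `(high_ppm, low_ppm)`.
#' @return numeric integral.
#' @export
window_integral <- function(spectrum, window) {
  idx <- ppm_index(spectrum, window)
  if (length(idx) < 2) stop("invalid_window: fewer than 2 points in window")
  hz <- spectrum$ppm[idx] * spectrum$params$spectrometer_freq
  y <- spectrum$real[idx]
  # ppm axis is descending; take the magnitude of the trapezoid sum
  abs(sum(diff(hz) * (y[-1] + y[-length(y)]) / 2))
}

#' Full width at half maximum of a peak
#'
#' Locates the tallest point in the window and measures the width at half
#' height with linear interpolation between samples.
#'
#' @param spectrum an `ars_spectrum`.
#' @param window `(high_ppm, low_ppm)` containing a single peak.
#' @return FWHM in Hz.
#' @export
fwhm_hz <- function(spectrum, window) {
  idx <- ppm_index(spectrum, window)
  y <- spectrum$real[idx]
  hz <- spectrum$ppm[idx] * spectrum$params$spectrometer_freq
  k <- which.max(y)
  half <- y[k] / 2
  left <- k
  while (left > 1 && y[left] > half) left <- left - 1
  right <- k
  while (right < length(y) && y[right] > half) right <- right + 1
  if (left == 1 || right == length(y))
    stop("invalid_window: peak half-height not bracketed by window")
  x_l <- hz[left] + (half - y[left]) / (y[left + 1] - y[left]) * (hz[left + 1] - hz[left])
  x_r <- hz[right - 1] + (half - y[right - 1]) / (y[right] - y[right - 1]) * (hz[right] - hz[right - 1])
  abs(x_l - x_r)
}

#' Digital resolution of a spectrum or FID
#'
#' @param x an `ars_spectrum` or `ars_fid`.
#' @return Hz per point.
#' @export
digital_resolution <- function(x) {
  n <- if (inherits(x, "ars_fid")) length(x$data) else length(x$real)
  x$params$sweep_width / n
}
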