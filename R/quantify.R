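#' Integration window
#'
#' @param center window center in ppm.
#' @param half_width half width in ppm (> 0). Default 0.10 ppm.
#' @param label window label.
#' @return an object of class `ars_window`.
#' @export
integration_window <- function(center, half_width = 0.10, label = "") {
  if (half_width <= 0) stop("invalid_window: half_width must be > 0")
  structure(list(center = center, half_width = half_width, label = label,
                 window = c(center + half_width, center - half_width)),
            class = "ars_window")
}

#' Default integration windows: ARS singlet and internal standard
#' @return named list with elements `ars` (6.00 +/- 0.10 ppm) and
#'   `is` (9.79 +/- 0.10 ppm).
#' @export
default_windows <- function() {
  k <- ars_constants()
  list(ars = integration_window(k$ars_shift, 0.10, "ARS H-2,4,6"),
       is = integration_window(k$is_shift, 0.10, "syringaldehyde CHO"))
}

#' Normalized integrals relative to the internal standard
#'
#' Trapezoidal areas of the real trace over each window, divided by the
#' internal-standard window area, which is set to 1 — the normalization
#' convention of the assay. Quantification is impossible without a usable
#' IS peak, so an IS area that is non-positive or below three times the
#' integrated noise level is an error.
#'
#' @param spectrum a processed `ars_spectrum`.
#' @param windows named list of [integration_window()]s; must contain `is`.
#'   Windows must not overlap.
#' @param noise_window signal-free region for the noise estimate.
#' @return named numeric vector of normalized integrals (element `is` is 1),
#'   with the raw areas in attribute `"raw"`.
#' @export
integrate_spectrum <- function(spectrum, windows = default_windows(),
                               noise_window = default_noise_region()) {
  if (is.null(windows$is)) stop("invalid_windows: an 'is' window is required")
  wins <- lapply(windows, function(w) w$window)
  nm <- names(wins)
  for (i in seq_along(wins)) for (j in seq_len(i - 1L)) {
    if (windows_overlap(wins[[i]], wins[[j]]))
      stop(sprintf("overlapping_windows: '%s' and '%s'", nm[i], nm[j]))
  }
  raw <- vapply(wins, window_integral, numeric(1), spectrum = spectrum)
  rms <- spectrum_noise_rms(spectrum, noise_window)
  # noise-equivalent area over the IS window
  span_hz <- 2 * windows$is$half_width * spectrum$params$spectrometer_freq
  noise_area <- rms * span_hz
  is_height <- max(spectrum$real[ppm_index(spectrum, wins[["is"]])])
  if (raw[["is"]] <= 0 || raw[["is"]] < 3 * noise_area ||
      is_height < 1e-4 * max(abs(spectrum$real)))
    stop("is_peak_missing: internal-standard area non-positive or below 3x noise")
  out <- raw / raw[["is"]]
  attr(out, "raw") <- raw
  out
}

#' Concentration from the normalized ARS integral
#'
#' Applies the internal-standard formula
#' `C = (I_ARS / 3) * mmol_IS / M_sample`: the 3-proton normalized ARS
#' integral is converted to moles via the 1-proton IS reference and divided
#' by the sample mass.
#'
#' @param i_ars normalized ARS integral (IS = 1).
#' @param is_mmol internal-standard amount in mmol (default the protocol
#'   constant 0.00270 for 0.5 mg syringaldehyde).
#' @param sample_mass sample portion in mg (> 0).
#' @param n_protons protons contributing to the ARS integral (3).
#' @return list with `c_mmol_per_mg` and `c_mmol_per_kg`.
#' @export
concentration <- function(i_ars, is_mmol = ars_constants()$is_mmol,
                          sample_mass = ars_constants()$sample_mass_mg,
                          n_protons = 3) {
  if (sample_mass <= 0) stop("invalid_sample_mass: sample_mass must be > 0")
  if (i_ars < 0 || is_mmol <= 0)
    stop("invalid_inputs: i_ars must be >= 0 and is_mmol > 0")
  c_mmol_per_mg <- (i_ars / n_protons) * is_mmol / sample_mass
  list(c_mmol_per_mg = c_mmol_per_mg,
       c_mmol_per_kg = c_mmol_per_mg * 1e6)
}

#' Convert mmol/Kg to mg/Kg via the average molecular weight
#'
#' @param c_mmol_per_kg concentration in mmol/Kg.
#' @param mw_avg average molecular weight in g/mol (default 390, the mean
#'   of the C19 and C21 homologs).
#' @return concentration in mg/Kg.
#' @export
to_mg_per_kg <- function(c_mmol_per_kg, mw_avg = ars_constants()$mw_avg) {
  if (mw_avg <= 0) stop("invalid_mw: mw_avg must be > 0")
  c_mmol_per_kg * mw_avg
}

#' Report-style rounding: mg/Kg to integer, mmol/Kg to two decimals
#' @param c_mg_per_kg concentration in mg/Kg.
#' @param c_mmol_per_kg concentration in mmol/Kg.
#' @return list of rounded values.
#' @export
report_rounding <- function(c_mg_per_kg, c_mmol_per_kg) {
  list(c_mg_per_kg = round(c_mg_per_kg),
       c_mmol_per_kg = round(c_mmol_per_kg, 2))
}

#' Signal-to-noise ratio of a peak
#'
#' S/N = peak maximum height divided by twice the RMS of a signal-free
#' noise region — the convention of common instrument software. A
#' noise-free spectrum returns `Inf`.
#'
#' @param spectrum an `ars_spectrum`.
#' @param peak_window an [integration_window()] containing the peak.
#' @param noise_window `(high_ppm, low_ppm)` signal-free region, disjoint
#'   from the peak window.
#' @param rms_factor divisor applied to the peak height per unit of noise
#'   RMS (default 2).
#' @return dimensionless S/N (Inf when the noise RMS is 0).
#' @export
snr <- function(spectrum, peak_window = default_windows()$ars,
                noise_window = default_noise_region(), rms_factor = 2) {
  if (windows_overlap(peak_window$window, noise_window))
    stop("overlapping_windows: noise window overlaps the peak window")
  idx <- ppm_index(spectrum, peak_window$window)
  if (length(idx) == 0) stop("invalid_window: empty peak window")
  height <- max(spectrum$real[idx])
  rms <- spectrum_noise_rms(spectrum, noise_window)
  # noise-free sentinel: an essentially empty noise region (far below the
  # dynamic range of any real measurement, where only far Lorentzian tails
  # remain) reports infinite S/N
  if (rms < 1e-5 * max(abs(spectrum$real))) return(Inf)
  max(0, height / (rms_factor * rms))
}

#' Detection call from S/N thresholds
#'
#' Classifies a measurement: S/N below 3 is "nd" (not detected), between 3
#' and 10 "below_loq" (detected but not quantifiable), and 10 or above
#' "quantified". Boundary values count as the higher category.
#'
#' @param c_mg_per_kg measured concentration in mg/Kg (carried through for
#'   reporting; not used in the call itself).
#' @param snr signal-to-noise ratio (>= 0).
#' @param lod_snr detection threshold (default 3).
#' @param loq_snr quantification threshold (default 10).
#' @return one of `"nd"`, `"below_loq"`, `"quantified"`.
#' @export
detection_call <- function(c_mg_per_kg, snr, lod_snr = 3, loq_snr = 10) {
  if (snr < 0) stop("invalid_snr: snr must be >= 0")
  if (snr < lod_snr) "nd" else if (snr < loq_snr) "below_loq" else "quantified"
}

#' Quantify a processed spectrum
#'
#' Runs the quantification stage on a processed spectrum: normalized
#' integration, the internal-standard concentration formula, unit
#' conversion and the S/N-based detection call. For "nd" results the
#' concentrations are reported but flagged as not detected.
#'
#' @param spectrum a processed `ars_spectrum`.
#' @param windows named list of integration windows (needs `ars` and `is`).
#' @param is_mmol internal-standard amount in mmol.
#' @param sample_mass sample portion in mg.
#' @param mw_avg average ARS molecular weight in g/mol.
#' @param lod_snr,loq_snr detection-call thresholds.
#' @param noise_window signal-free region for noise estimation.
#' @return an object of class `ars_quant`: list with `i_ars`,
#'   `c_mmol_per_kg`, `c_mg_per_kg`, `snr`, `status`, `is_mmol`,
#'   `sample_mass`, `mw_avg`.
#' @export
quantify_spectrum <- function(spectrum, windows = default_windows(),
                              is_mmol = ars_constants()$is_mmol,
                              sample_mass = ars_constants()$sample_mass_mg,
                              mw_avg = ars_constants()$mw_avg,
                              lod_snr = 3, loq_snr = 10,
                              noise_window = default_noise_region()) {
  ints <- integrate_spectrum(spectrum, windows, noise_window)
  i_ars <- max(0, unname(ints[["ars"]]))
  conc <- concentration(i_ars, is_mmol, sample_mass)
  c_mg <- to_mg_per_kg(conc$c_mmol_per_kg, mw_avg)
  s <- snr(spectrum, windows$ars, noise_window)
  status <- detection_call(c_mg, s, lod_snr, loq_snr)
  structure(list(i_ars = i_ars,
                 c_mmol_per_kg = conc$c_mmol_per_kg,
                 c_mg_per_kg = c_mg,
                 snr = s,
                 status = status,
                 is_mmol = is_mmol,
                 sample_mass = sample_mass,
                 mw_avg = mw_avg),
            class = "ars_quant")
}

#' @export
print.ars_quant <- function(x, ...) {
  r <- report_rounding(x$c_mg_per_kg, x$c_mmol_per_kg)
  shown <- if (x$status == "nd") "ND" else
    sprintf("%d mg/Kg (%.2f mmol/Kg)", r$c_mg_per_kg, r$c_mmol_per_kg)
  cat(sprintf("total ARS: %s   [i_ars=%.4f, S/N=%s, %s]\n", shown, x$i_ars,
              if (is.finite(x$snr)) sprintf("%.1f", x$snr) else "Inf",
              x$status))
  invisible(x)
}

#' Simulate, process and quantify one sample
#'
#' End-to-end convenience path: extract resonances, synthesize the FID,
#' run the processing chain and quantify.
#'
#' @param sample an [sample_spec()] object.
#' @param params an [acq_params()] object.
#' @param noise_sigma per-scan noise sd.
#' @param seed RNG seed (defaults to the sample's).
#' @param phase_with phasing mode for [process_fid()]. Simulated spectra
#'   are generated in absorption mode, so the exact manual zero correction
#'   is the cheap default; use `"auto"` to exercise the automatic phaser.
#' @param ... passed to [extract_resonances()].
#' @return an `ars_quant`.
#' @export
quantify_sample <- function(sample, params = acq_params(),
                            noise_sigma = default_noise_sigma(),
                            seed = sample$seed,
                            phase_with = phase_params(0, 0), ...) {
  fid <- simulate_sample(sample, params, noise_sigma, seed, ...)
  spec <- process_fid(fid, phase_with = phase_with)
  quantify_spectrum(spec, sample_mass = sample$sample_mass)
}

#' Quantification report over several samples
#'
#' @param samples list of `ars_sample` objects.
#' @param ... passed to [quantify_sample()].
#' @return data.frame with columns `sample`, `i_ars`, `snr`,
#'   `c_mg_per_kg`, `c_mmol_per_kg`, `status` (report rounding applied;
#'   ND rows carry NA concentrations).
#' @export
quantify_report <- function(samples, ...) {
  rows <- lapply(samples, function(s) {
    q <- quantify_sample(s, ...)
    r <- report_rounding(q$c_mg_per_kg, q$c_mmol_per_kg)
    data.frame(sample = s$matrix_name,
               i_ars = round(q$i_ars, 4),
               snr = if (is.finite(q$snr)) round(q$snr, 1) else Inf,
               c_mg_per_kg = if (q$status == "nd") NA else r$c_mg_per_kg,
               c_mmol_per_kg = if (q$status == "nd") NA else r$c_mmol_per_kg,
               status = q$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a quantification report CSV with a provenance header
#'
#' @param report data.frame from [quantify_report()].
#' @param path output path.
#' @param config optional [run_config()] whose constants are echoed as
#'   comment lines.
#' @return path, invisibly.
#' @export
write_report_csv <- function(report, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    for (line in config_provenance(config)) writeLines(paste0("# ", line), con)
  }
  write.csv(report, con, row.names = FALSE)
  invisible(path)
}
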