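#' Acquisition parameters for a 1D 1H experiment
#'
#' Container for the pulse-program constants of the high-throughput
#' alkylresorcinol assay: a standard one-pulse 1H experiment on a 400 MHz
#' instrument, 16 scans into 32 K data points over 5263.18 Hz, relaxation
#' delay 10 s, acquisition time 3.11 s, measured at 298 K.
#'
#' `td_points` counts real + imaginary points (instrument convention), so
#' the stored complex FID has `td_points / 2` points and
#' `acquisition_time = td_points / (2 * sweep_width)`.
#'
#' @param spectrometer_freq 1H frequency in MHz.
#' @param sweep_width spectral width in Hz.
#' @param td_points number of real+imaginary time-domain points.
#' @param relaxation_delay inter-scan delay d1 in seconds.
#' @param n_scans number of accumulated scans.
#' @param line_broadening_default exponential line broadening in Hz applied
#'   by the default processing chain.
#' @param temperature sample temperature in K.
#' @param pulse_angle excitation pulse angle in degrees.
#' @param ref_ppm chemical shift assigned to the carrier (mid-sweep)
#'   frequency; the axis is refined later by [calibrate_ppm()].
#' @param acquisition_time acquisition time in s; derived from
#'   `td_points / (2 * sweep_width)` when `NULL`. A supplied value must
#'   agree with the derived one within 1%.
#' @return An object of class `ars_acq`.
#' @export
acq_params <- function(spectrometer_freq = 400,
                       sweep_width = 5263.18,
                       td_points = 32768,
                       relaxation_delay = 10,
                       n_scans = 16,
                       line_broadening_default = 0.3,
                       temperature = 298,
                       pulse_angle = 90,
                       ref_ppm = 6.5,
                       acquisition_time = NULL) {
  if (sweep_width <= 0) stop("invalid_acq_params: sweep_width must be > 0")
  if (n_scans < 1) stop("invalid_acq_params: n_scans must be >= 1")
  if (td_points < 4 || td_points %% 2 != 0)
    stop("invalid_acq_params: td_points must be an even count of real+imaginary points")
  aq_derived <- td_points / (2 * sweep_width)
  if (is.null(acquisition_time)) {
    acquisition_time <- aq_derived
  } else if (abs(acquisition_time - aq_derived) > 0.01 * aq_derived) {
    stop("invalid_acq_params: acquisition_time inconsistent with td_points / (2 * sweep_width)")
  }
  structure(list(
    spectrometer_freq = spectrometer_freq,
    sweep_width = sweep_width,
    td_points = td_points,
    acquisition_time = acquisition_time,
    relaxation_delay = relaxation_delay,
    n_scans = n_scans,
    line_broadening_default = line_broadening_default,
    temperature = temperature,
    pulse_angle = pulse_angle,
    ref_ppm = ref_ppm
  ), class = "ars_acq")
}

#' @export
print.ars_acq <- function(x, ...) {
  cat(sprintf(
    "1H acquisition: %.0f MHz, sweep %.2f Hz, TD %d (aq %.3f s), d1 %g s, %d scans, %g K\n",
    x$spectrometer_freq, x$sweep_width, x$td_points, x$acquisition_time,
    x$relaxation_delay, x$n_scans, x$temperature))
  invisible(x)
}

#' ppm extent of the sweep window
#' @param params an `ars_acq` object.
#' @return c(high_ppm, low_ppm) covered by the sweep.
#' @export
sweep_window_ppm <- function(params) {
  half <- params$sweep_width / (2 * params$spectrometer_freq)
  c(params$ref_ppm + half, params$ref_ppm - half)
}

#' A single simulated resonance
#'
#' One Lorentzian line: chemical shift, number of equivalent protons, amount
#' of substance and relaxation times. Default T2 of 1/pi s gives a natural
#' linewidth of 1.0 Hz (sharp singlet).
#'
#' @param shift chemical shift in ppm.
#' @param n_protons number of equivalent protons (integer >= 1).
#' @param amount amount of substance in mmol (>= 0).
#' @param t2 transverse relaxation time in s.
#' @param t1 longitudinal relaxation time in s; must satisfy t1 >= t2.
#' @param label free-text label.
#' @return An object of class `ars_resonance`.
#' @export
resonance <- function(shift, n_protons, amount, t2 = 1 / pi, t1 = 2 * t2,
                      label = "") {
  n_protons <- as.integer(n_protons)
  if (n_protons < 1) stop("invalid_resonance: n_protons must be >= 1")
  if (amount < 0) stop("invalid_resonance: amount must be >= 0")
  if (!(t1 >= t2 && t2 > 0)) stop("invalid_resonance: need t1 >= t2 > 0")
  structure(list(shift = shift, n_protons = n_protons, amount = amount,
                 t2 = t2, t1 = t1, label = label),
            class = "ars_resonance")
}

# default relaxation times: chosen so the d1 sweep (1,2,5,8,10,15,20 s)
# converges by 10 s with the 3.11 s acquisition time
T1_ARS_DEFAULT <- 1.2
T1_IS_DEFAULT <- 2.5

#' Protocol constants of the assay
#'
#' Molecular-weight and internal-standard constants used throughout:
#' the average ARS molecular weight of 390 g/mol (arithmetic mean of the
#' C19 homolog at m/z 376 and the C21 homolog at m/z 404, the dominant side
#' chains in wheat), the syringaldehyde internal-standard amount of
#' 0.00270 mmol for 0.5 mg (the protocol's printed constant; the exact value
#' from MW 182.17 g/mol is available via `use_true_is_mw`), and the default
#' 330 mg sample portion.
#'
#' @param use_true_is_mw if TRUE, compute the IS amount as
#'   0.5 mg / 182.17 g/mol = 0.002745 mmol instead of the protocol constant
#'   0.00270.
#' @return Named list of constants.
#' @export
ars_constants <- function(use_true_is_mw = FALSE) {
  list(
    mw_c19 = 376,
    mw_c21 = 404,
    mw_avg = (376 + 404) / 2,
    mw_syringaldehyde = 182.17,
    is_mass_mg = 0.5,
    is_mmol = if (use_true_is_mw) 0.5 / 182.17 else 0.00270,
    sample_mass_mg = 330,
    ars_shift = 6.00,
    ars_protons = 3L,
    is_shift = 9.79,
    is_protons = 1L,
    dmso_shift = 2.50,
    lod_snr = 3,
    loq_snr = 10
  )
}

#' Specification of one simulated sample
#'
#' Describes a flour/grain/product sample as analyzed by the assay: its
#' total alkylresorcinol concentration, the weighed portion, the internal
#' standard addition and the extraction model (per-cycle efficiency).
#'
#' @param matrix_name sample description, e.g. "T. monococcum, whole-grain flour".
#' @param ars_mg_per_kg total ARS concentration in mg/Kg (0 for ARS-free
#'   matrices such as white flour).
#' @param sample_mass weighed portion in mg (default 330).
#' @param is_mass internal standard mass in mg (default 0.5, in 1 mL DMSO-d6).
#' @param is_solution_volume extraction solvent volume in mL.
#' @param extraction_efficiency fraction of the remaining pool recovered per
#'   extraction cycle, in (0, 1].
#' @param extraction_cycles number of extraction cycles performed.
#' @param seed mandatory RNG seed; all randomness in the simulator derives
#'   from it.
#' @return An object of class `ars_sample`.
#' @export
sample_spec <- function(matrix_name, ars_mg_per_kg, sample_mass = 330,
                        is_mass = 0.5, is_solution_volume = 1,
                        extraction_efficiency = 0.96,
                        extraction_cycles = 1L, seed) {
  if (missing(seed)) stop("invalid_sample_spec: seed is mandatory")
  if (extraction_efficiency <= 0 || extraction_efficiency > 1)
    stop("invalid_sample_spec: extraction_efficiency must lie in (0, 1]")
  if (sample_mass <= 0) stop("invalid_sample_spec: sample_mass must be > 0")
  if (ars_mg_per_kg < 0) stop("invalid_sample_spec: ars_mg_per_kg must be >= 0")
  structure(list(matrix_name = matrix_name,
                 ars_mg_per_kg = ars_mg_per_kg,
                 sample_mass = sample_mass,
                 is_mass = is_mass,
                 is_solution_volume = is_solution_volume,
                 extraction_efficiency = extraction_efficiency,
                 extraction_cycles = as.integer(extraction_cycles),
                 seed = as.integer(seed)),
            class = "ars_sample")
}

#' @export
print.ars_sample <- function(x, ...) {
  cat(sprintf("sample '%s': %g mg ARS/Kg, %g mg portion, IS %g mg, eff %.2f/cycle, seed %d\n",
              x$matrix_name, x$ars_mg_per_kg, x$sample_mass, x$is_mass,
              x$extraction_efficiency, x$seed))
  invisible(x)
}

#' Published sample presets
#'
#' The flour, grain and processed-product concentrations reported by the
#' assay (total ARS in mg/Kg and mmol/Kg). `conversion_exact` marks rows
#' whose printed mmol/Kg column equals mg/Kg divided by 390 after rounding
#' to two decimals; the two rows where the printed columns disagree with
#' that conversion (T. aestivum whole-grain flour, and the T. dicoccum
#' grain rounding edge) are flagged FALSE. ND rows carry `NA` mmol and 0 mg.
#'
#' @return data.frame with columns `preset`, `matrix_name`, `ars_mg_per_kg`,
#'   `mmol_per_kg_printed`, `category`, `conversion_exact`.
#' @export
published_presets <- function() {
  df <- data.frame(
    preset = c(
      "t_monococcum_wholegrain", "secale_cereale_wholegrain",
      "t_dicoccum_wholegrain", "t_durum_wholegrain",
      "t_aestivum_wholegrain", "t_turgidum_wholegrain",
      "t_aestivum_white",
      "t_dicoccum_grain", "t_monococcum_grain", "t_aestivum_grain",
      "t_durum_deveta_grain", "t_durum_dourouki_grain",
      "t_dicoccum_bread", "t_dicoccum_flakes", "t_dicoccum_wafers",
      "t_dicoccum_pasta", "t_monococcum_flakes", "t_aestivum_white_bread"),
    matrix_name = c(
      "T. monococcum, whole-grain flour", "Secale cereale, whole-grain flour",
      "T. dicoccum, whole-grain flour", "T. durum, whole-grain flour",
      "T. aestivum, whole-grain flour", "T. turgidum, whole-grain flour",
      "T. aestivum, white flour",
      "T. dicoccum grain", "T. monococcum grain", "T. aestivum grain",
      "T. durum (cv. deveta) grain", "T. durum (cv. dourouki) grain",
      "T. dicoccum bread (whole-grain flour)", "T. dicoccum flakes",
      "T. dicoccum wafers", "T. dicoccum pasta", "T. monococcum flakes",
      "T. aestivum bread (white flour)"),
    ars_mg_per_kg = c(638, 574, 510, 191, 121, 63, 0,
                      1148, 925, 255, 255, 191,
                      455, 1090, 351, 330, 1084, 0),
    mmol_per_kg_printed = c(1.64, 1.47, 1.31, 0.49, 0.33, 0.16, NA,
                            2.95, 2.37, 0.65, 0.65, 0.49,
                            1.17, 2.79, 0.90, 0.85, 2.78, NA),
    category = c(rep("flour", 7), rep("grain", 5), rep("product", 6)),
    stringsAsFactors = FALSE
  )
  df$conversion_exact <- !is.na(df$mmol_per_kg_printed) &
    round(df$ars_mg_per_kg / ars_constants()$mw_avg, 2) == df$mmol_per_kg_printed
  df
}

#' Build a sample_spec from a named preset
#'
#' @param preset preset id, one of `published_presets()$preset`.
#' @param seed mandatory RNG seed.
#' @param ... further arguments passed to [sample_spec()].
#' @return An `ars_sample`.
#' @export
preset_sample <- function(preset, seed, ...) {
  tab <- published_presets()
  i <- match(preset, tab$preset)
  if (is.na(i)) {
    stop(sprintf("unknown_preset: '%s'; available presets: %s",
                 preset, paste(tab$preset, collapse = ", ")))
  }
  sample_spec(matrix_name = tab$matrix_name[i],
              ars_mg_per_kg = tab$ars_mg_per_kg[i], seed = seed, ...)
}
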