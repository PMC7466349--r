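#' Run configuration
#'
#' Bundles every tunable of the pipeline with its protocol default:
#' acquisition parameters, integration windows, noise model, quantification
#' constants and detection thresholds. Any value overridden away from its
#' default is recorded and echoed into output provenance blocks.
#'
#' @param ... overrides of the default entries (unknown names are an error).
#' @return an object of class `ars_config`.
#' @export
run_config <- function(...) {
  k <- ars_constants()
  defaults <- list(
    acq = acq_params(),
    windows = default_windows(),
    noise_sigma = default_noise_sigma(),
    is_mmol = k$is_mmol,
    mw_avg = k$mw_avg,
    sample_mass = k$sample_mass_mg,
    lod_snr = k$lod_snr,
    loq_snr = k$loq_snr,
    line_broadening = 0.3,
    zero_fill_factor = 2L,
    baseline_degree = 3,
    seed = 1L,
    out_dir = "results"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("invalid_config: unknown option(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, overrides)
  cfg$overridden <- names(overrides)
  structure(cfg, class = "ars_config")
}

#' Provenance lines for a configuration
#'
#' Flat key: value lines describing the constants, windows and seed of a
#' run, suitable for embedding in report headers.
#'
#' @param config an `ars_config`.
#' @return character vector.
#' @export
config_provenance <- function(config) {
  a <- config$acq
  lines <- c(
    sprintf("package: arsqnmr %s", as.character(utils::packageVersion("arsqnmr"))),
    sprintf("spectrometer_freq_mhz: %g", a$spectrometer_freq),
    sprintf("sweep_width_hz: %g", a$sweep_width),
    sprintf("td_points: %d", a$td_points),
    sprintf("acquisition_time_s: %g", a$acquisition_time),
    sprintf("relaxation_delay_s: %g", a$relaxation_delay),
    sprintf("n_scans: %d", a$n_scans),
    sprintf("line_broadening_hz: %g", config$line_broadening),
    sprintf("zero_fill_factor: %d", config$zero_fill_factor),
    sprintf("ars_window_ppm: %g +/- %g", config$windows$ars$center,
            config$windows$ars$half_width),
    sprintf("is_window_ppm: %g +/- %g", config$windows$is$center,
            config$windows$is$half_width),
    sprintf("is_mmol: %g", config$is_mmol),
    sprintf("mw_avg_g_per_mol: %g", config$mw_avg),
    sprintf("sample_mass_mg: %g", config$sample_mass),
    sprintf("lod_snr: %g / loq_snr: %g", config$lod_snr, config$loq_snr),
    sprintf("noise_sigma: %g", config$noise_sigma),
    sprintf("seed: %d", config$seed)
  )
  if (length(config$overridden) > 0)
    lines <- c(lines, sprintf("overridden: %s",
                              paste(config$overridden, collapse = ", ")))
  lines
}

#' @export
print.ars_config <- function(x, ...) {
  cat(paste(config_provenance(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Write a configuration as a flat key=value text file
#' @param config an `ars_config`.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_config <- function(config, path) {
  a <- config$acq
  kv <- c(
    spectrometer_freq = a$spectrometer_freq, sweep_width = a$sweep_width,
    td_points = a$td_points, relaxation_delay = a$relaxation_delay,
    n_scans = a$n_scans, line_broadening = config$line_broadening,
    zero_fill_factor = config$zero_fill_factor,
    baseline_degree = config$baseline_degree,
    noise_sigma = config$noise_sigma, is_mmol = config$is_mmol,
    mw_avg = config$mw_avg, sample_mass = config$sample_mass,
    lod_snr = config$lod_snr, loq_snr = config$loq_snr, seed = config$seed)
  writeLines(sprintf("%s=%s", names(kv), format(kv, scientific = FALSE,
                                                trim = TRUE)), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#' @param path file written by [write_config()] (unknown keys are an error).
#' @return an `ars_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file_not_found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  kv <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                        vapply(parts, `[`, character(1), 1))
  acq_keys <- c("spectrometer_freq", "sweep_width", "td_points",
                "relaxation_delay", "n_scans")
  acq_over <- as.list(kv[intersect(names(kv), acq_keys)])
  if ("td_points" %in% names(acq_over))
    acq_over$td_points <- as.integer(acq_over$td_points)
  if ("n_scans" %in% names(acq_over))
    acq_over$n_scans <- as.integer(acq_over$n_scans)
  other <- as.list(kv[setdiff(names(kv), acq_keys)])
  for (nm in c("zero_fill_factor", "baseline_degree", "seed"))
    if (nm %in% names(other)) other[[nm]] <- as.integer(other[[nm]])
  do.call(run_config, c(list(acq = do.call(acq_params, acq_over)), other))
}
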