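#' Recovery study over successive extraction cycles
#'
#' Simulates the extract of each extraction cycle separately (fresh
#' internal standard per cycle), quantifies each, and reports per-cycle
#' recovered fractions — each cycle's concentration divided by the sum over
#' all cycles, the model-free estimate used when recovery is judged from
#' successive extractions. Under the single-pool model the fractions follow
#' the geometric series `eff * (1 - eff)^(k-1)`.
#'
#' @param sample an [sample_spec()] object.
#' @param cycles number of cycles (>= 2).
#' @param params an [acq_params()] object.
#' @param noise_sigma per-scan noise sd (default 0: recovery is a
#'   deterministic property of the extraction model).
#' @param lod_mg_per_kg detection floor: an error is raised if the summed
#'   quantified concentration falls below it.
#' @return list with `recovery_by_cycle`, `cumulative_recovery` (estimated
#'   pool fraction captured by the performed cycles) and
#'   `conc_by_cycle_mg_per_kg`.
#' @export
recovery_study <- function(sample, cycles = 3, params = acq_params(),
                           noise_sigma = 0, lod_mg_per_kg = 30) {
  if (cycles < 2) stop("invalid_cycles: need at least 2 cycles")
  conc <- vapply(seq_len(cycles), function(k) {
    amt <- extract(sample, k)$amount_mmol
    fid <- synthesize_fid(
      extract_resonances(sample, ars_amount_mmol = amt),
      params, noise_sigma = noise_sigma, seed = sample$seed + k,
      provenance = sprintf("recovery cycle %d", k))
    spec <- process_fid(fid, phase_with = phase_params(0, 0))
    q <- quantify_spectrum(spec, sample_mass = sample$sample_mass)
    q$c_mg_per_kg
  }, numeric(1))
  total <- sum(conc)
  if (total < lod_mg_per_kg)
    stop("below_lod: total recovered concentration below the detection limit")
  frac <- conc / total
  eff_hat <- frac[1]
  list(recovery_by_cycle = frac,
       cumulative_recovery = 1 - (1 - eff_hat)^cycles,
       conc_by_cycle_mg_per_kg = conc)
}

#' Intraday and interday precision
#'
#' Repeated quantification of the same sample: `replicates` independent
#' simulated measurements per day over `days` days. Interday variation is
#' modeled as a deterministic per-day multiplicative factor drawn uniformly
#' from +/- `day_effect` under the study seed. %RSD = 100 * sd / mean of
#' the measured mg/Kg, within day (averaged across days) and across all
#' measurements.
#'
#' @param sample an [sample_spec()] object; must be quantifiable (above
#'   LOQ), otherwise a named error is raised.
#' @param replicates measurements per day (>= 2).
#' @param days number of days.
#' @param params an [acq_params()] object.
#' @param noise_sigma per-scan noise sd.
#' @param day_effect amplitude of the per-day multiplicative perturbation
#'   (default 0.02 = +/-2%).
#' @param seed study seed; replicate seeds are derived from it.
#' @return list with `rsd_intraday`, `rsd_interday` (both %),
#'   `measurements` (days x replicates matrix of mg/Kg) and `day_factors`.
#' @export
precision_study <- function(sample, replicates = 3, days = 3,
                            params = acq_params(),
                            noise_sigma = default_noise_sigma(),
                            day_effect = 0.02, seed = sample$seed) {
  if (replicates < 2) stop("invalid_replicates: need at least 2 replicates")
  day_factors <- if (day_effect > 0) {
    with_seed(seed, 1 + runif(days, -day_effect, day_effect))
  } else rep(1, days)
  meas <- matrix(NA_real_, nrow = days, ncol = replicates)
  for (d in seq_len(days)) {
    day_sample <- sample
    day_sample$ars_mg_per_kg <- sample$ars_mg_per_kg * day_factors[d]
    for (r in seq_len(replicates)) {
      q <- quantify_sample(day_sample, params, noise_sigma,
                           seed = seed + 1000L * d + r)
      if (d == 1 && r == 1 && q$status != "quantified")
        stop("below_loq: precision is undefined for a sample below the quantification limit")
      meas[d, r] <- q$c_mg_per_kg
    }
  }
  rsd <- function(x) if (mean(x) == 0) 0 else 100 * sd(x) / mean(x)
  intraday <- mean(apply(meas, 1, rsd))
  list(rsd_intraday = intraday,
       rsd_interday = rsd(as.vector(meas)),
       measurements = meas,
       day_factors = day_factors)
}

#' LOD/LOQ by linear S/N scaling
#'
#' Extrapolates the detection (S/N = 3) and quantification (S/N = 10)
#' limits from one measured S/N at a known concentration, assuming S/N is
#' linear in concentration, and converts between mg/Kg and absolute
#' micrograms in the analyzed portion. Pre-rounding, `loq / lod = 10 / 3`
#' exactly by construction.
#'
#' @param conc_mg_per_kg concentration of the measured sample in mg/Kg.
#' @param snr measured signal-to-noise ratio (> 0, finite).
#' @param sample_mass analyzed portion in mg.
#' @param lod_snr,loq_snr S/N thresholds (3 and 10).
#' @return list with `lod_mg_per_kg`, `loq_mg_per_kg`, `lod_ug`, `loq_ug`.
#' @export
lod_loq <- function(conc_mg_per_kg, snr, sample_mass = 330,
                    lod_snr = 3, loq_snr = 10) {
  if (!is.finite(snr) || snr <= 0)
    stop("invalid_snr: a finite positive S/N is required")
  lod <- lod_snr * conc_mg_per_kg / snr
  loq <- loq_snr * conc_mg_per_kg / snr
  list(lod_mg_per_kg = lod, loq_mg_per_kg = loq,
       lod_ug = mg_per_kg_to_ug(lod, sample_mass),
       loq_ug = mg_per_kg_to_ug(loq, sample_mass))
}

#' Convert an absolute analyte mass to a sample concentration
#' @param ug analyte micrograms in the analyzed portion.
#' @param sample_mass portion mass in mg.
#' @return concentration in mg/Kg.
#' @export
ug_to_mg_per_kg <- function(ug, sample_mass = 330) ug * 1e3 / sample_mass

#' Convert a sample concentration to an absolute analyte mass
#' @param mg_per_kg concentration in mg/Kg.
#' @param sample_mass portion mass in mg.
#' @return analyte micrograms in the analyzed portion.
#' @export
mg_per_kg_to_ug <- function(mg_per_kg, sample_mass = 330)
  mg_per_kg * sample_mass * 1e-3

#' Relaxation-delay sufficiency sweep
#'
#' Simulates the sample noise-free at each relaxation delay and computes
#' the ARS/IS integral ratio. The sufficient delay is the first delay in
#' the list from which every subsequent step changes the ratio by less
#' than `tolerance` (relative) — the point where the ratio "remains
#' unchanged". If no delay satisfies this, the result is flagged
#' unconverged rather than raising an error.
#'
#' @param sample an [sample_spec()] object.
#' @param delays ascending delays in s (default 1, 2, 5, 8, 10, 15, 20).
#' @param tolerance relative change threshold (default 0.005).
#' @param params base [acq_params()]; the relaxation delay is swept.
#' @param ... passed to [extract_resonances()] (e.g. `t1_ars`, `t1_is`).
#' @return list with `table` (data.frame delay/ratio), `sufficient_delay`
#'   (NA if unconverged) and `converged`.
#' @export
delay_sweep <- function(sample, delays = c(1, 2, 5, 8, 10, 15, 20),
                        tolerance = 0.005, params = acq_params(), ...) {
  if (is.unsorted(delays, strictly = TRUE))
    stop("invalid_delays: delays must be strictly ascending")
  ratios <- vapply(delays, function(d1) {
    p <- params
    p$relaxation_delay <- d1
    fid <- synthesize_fid(extract_resonances(sample, ...),
                          p, noise_sigma = 0, seed = sample$seed,
                          provenance = sprintf("delay sweep d1=%g", d1))
    spec <- process_fid(fid, phase_with = phase_params(0, 0))
    unname(integrate_spectrum(spec)[["ars"]])
  }, numeric(1))
  rel_change <- abs(diff(ratios)) / ratios[-length(ratios)]
  ok <- vapply(seq_along(rel_change), function(i) all(rel_change[i:length(rel_change)] < tolerance),
               logical(1))
  suff <- if (any(ok)) delays[which(ok)[1]] else NA_real_
  list(table = data.frame(delay_s = delays, ars_is_ratio = ratios),
       sufficient_delay = suff,
       converged = !is.na(suff))
}

#' Closed-form saturation factor
#'
#' `1 - exp(-(relaxation_delay + acquisition_time) / t1)`: the fraction of
#' equilibrium longitudinal magnetization recovered between scans.
#'
#' @param relaxation_delay d1 in s.
#' @param acquisition_time aq in s.
#' @param t1 longitudinal relaxation time in s.
#' @return saturation factor in (0, 1).
#' @export
saturation_factor <- function(relaxation_delay, acquisition_time, t1)
  1 - exp(-(relaxation_delay + acquisition_time) / t1)

#' Full method-validation report
#'
#' Runs the recovery study, the precision study, the S/N-based LOD/LOQ
#' extrapolation and the relaxation-delay sweep on one sample.
#'
#' @param sample an [sample_spec()] object (above LOQ).
#' @param params an [acq_params()] object.
#' @param noise_sigma per-scan noise sd for the precision/LOD stages.
#' @param cycles extraction cycles for the recovery study.
#' @param seed study seed.
#' @return an object of class `ars_validation`: list with
#'   `recovery_by_cycle`, `cumulative_recovery`, `rsd_intraday`,
#'   `rsd_interday`, `lod_mg_per_kg`, `loq_mg_per_kg`, `lod_ug`, `loq_ug`,
#'   `delay_sweep`, `seed`.
#' @export
validation_report <- function(sample, params = acq_params(),
                              noise_sigma = default_noise_sigma(),
                              cycles = 3, seed = sample$seed) {
  rec <- recovery_study(sample, cycles, params)
  prec <- precision_study(sample, params = params, noise_sigma = noise_sigma,
                          seed = seed)
  q <- quantify_sample(sample, params, noise_sigma, seed = seed)
  lim <- lod_loq(q$c_mg_per_kg, q$snr, sample$sample_mass)
  ds <- delay_sweep(sample, params = params)
  structure(list(recovery_by_cycle = rec$recovery_by_cycle,
                 cumulative_recovery = rec$cumulative_recovery,
                 rsd_intraday = prec$rsd_intraday,
                 rsd_interday = prec$rsd_interday,
                 lod_mg_per_kg = lim$lod_mg_per_kg,
                 loq_mg_per_kg = lim$loq_mg_per_kg,
                 lod_ug = lim$lod_ug, loq_ug = lim$loq_ug,
                 delay_sweep = ds, seed = seed),
            class = "ars_validation")
}

#' @export
print.ars_validation <- function(x, ...) {
  cat("method validation summary\n")
  cat(sprintf("  recovery by cycle: %s (cumulative %.4f)\n",
              paste(sprintf("%.3f", x$recovery_by_cycle), collapse = ", "),
              x$cumulative_recovery))
  cat(sprintf("  %%RSD intraday %.2f, interday %.2f\n",
              x$rsd_intraday, x$rsd_interday))
  cat(sprintf("  LOD %.1f mg/Kg (%.1f ug), LOQ %.1f mg/Kg (%.1f ug)\n",
              x$lod_mg_per_kg, x$lod_ug, x$loq_mg_per_kg, x$loq_ug))
  cat(sprintf("  sufficient relaxation delay: %s s (converged: %s)\n",
              format(x$delay_sweep$sufficient_delay), x$delay_sweep$converged))
  invisible(x)
}

#' Serialize a validation report: CSV tables plus a text summary
#'
#' @param report an `ars_validation`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_validation_report <- function(report, dir, prefix = "validation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  stats_df <- data.frame(
    metric = c(sprintf("recovery_cycle_%d", seq_along(report$recovery_by_cycle)),
               "cumulative_recovery", "rsd_intraday_pct", "rsd_interday_pct",
               "lod_mg_per_kg", "loq_mg_per_kg", "lod_ug", "loq_ug",
               "sufficient_delay_s", "seed"),
    value = c(report$recovery_by_cycle, report$cumulative_recovery,
              report$rsd_intraday, report$rsd_interday,
              report$lod_mg_per_kg, report$loq_mg_per_kg,
              report$lod_ug, report$loq_ug,
              report$delay_sweep$sufficient_delay, report$seed))
  write.csv(stats_df, csv, row.names = FALSE)
  sweep_csv <- file.path(dir, paste0(prefix, "_delay_sweep.csv"))
  write.csv(report$delay_sweep$table, sweep_csv, row.names = FALSE)
  txt <- file.path(dir, paste0(prefix, ".txt"))
  sink(txt); print(report); sink()
  invisible(c(stats = csv, delay_sweep = sweep_csv, summary = txt))
}
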