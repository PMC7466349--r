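make_pair_spectrum <- function(ars_mmol, is_mmol = 0.00270, t1 = 2.5,
                               extra = list()) {
  res <- c(list(resonance(9.79, 1L, is_mmol, t1 = t1, label = "IS")),
           if (ars_mmol > 0) list(resonance(6.00, 3L, ars_mmol, t1 = t1,
                                            label = "ARS")),
           extra)
  fid <- synthesize_fid(res, noise_sigma = 0, seed = 1)
  process_fid(fid, phase_with = phase_params(0, 0), calibrate = FALSE)
}

test_that("integration normalizes to the internal standard set to 1", {
  # ARS amount chosen so 3 protons give 0.601 x the 1-proton IS reference
  sp <- make_pair_spectrum(ars_mmol = 0.601 * 0.00270 / 3)
  ints <- integrate_spectrum(sp)
  expect_equal(unname(ints[["is"]]), 1)
  expect_rel_equal(unname(ints[["ars"]]), 0.601, 0.01)
  raw <- attr(ints, "raw")
  expect_equal(unname(ints[["ars"]]), unname(raw[["ars"]] / raw[["is"]]))
})

test_that("quantification without a usable internal standard is an error", {
  res <- list(resonance(6.00, 3L, 5e-4, t1 = 2.5))
  fid <- synthesize_fid(res, noise_sigma = 0, seed = 1)
  sp <- process_fid(fid, phase_with = phase_params(0, 0), calibrate = FALSE)
  expect_error(integrate_spectrum(sp), "is_peak_missing")
})

test_that("overlapping integration windows are rejected", {
  sp <- make_pair_spectrum(5e-4)
  wins <- list(ars = integration_window(6.00, 0.10),
               is = integration_window(6.05, 0.10))
  expect_error(integrate_spectrum(sp, wins), "overlapping_windows")
  expect_error(integration_window(6.0, 0), "invalid_window")
})

test_that("the internal-standard formula gives C = (I/3) x mmol_IS / M", {
  conc <- concentration(0.601, 0.00270, 330)
  expect_equal(conc$c_mmol_per_kg, (0.601 / 3) * 0.00270 / 330 * 1e6)
  expect_equal(round(conc$c_mmol_per_kg, 2), 1.64)
  expect_equal(concentration(0, 0.00270, 330)$c_mmol_per_kg, 0)
  # linear in i_ars and is_mmol, inverse-linear in mass
  expect_equal(concentration(1.202, 0.00270, 330)$c_mmol_per_kg,
               2 * conc$c_mmol_per_kg)
  expect_equal(concentration(0.601, 0.00540, 330)$c_mmol_per_kg,
               2 * conc$c_mmol_per_kg)
  expect_equal(concentration(0.601, 0.00270, 660)$c_mmol_per_kg,
               conc$c_mmol_per_kg / 2)
  expect_equal(round(concentration(0.601, 0.00270, 660)$c_mmol_per_kg, 2), 0.82)
  expect_error(concentration(0.601, sample_mass = 0), "invalid_sample_mass")
})

test_that("unit conversion via MW 390 matches the published table", {
  tab <- published_presets()
  consistent <- tab[tab$conversion_exact, ]
  expect_gte(nrow(consistent), 10)
  for (i in seq_len(nrow(consistent))) {
    mmol <- consistent$ars_mg_per_kg[i] / 390
    expect_equal(round(mmol, 2), consistent$mmol_per_kg_printed[i])
  }
  # mg/Kg = mmol/Kg x MW holds exactly pre-rounding
  expect_equal(to_mg_per_kg(1.17), 456.3)
  expect_equal(to_mg_per_kg(0), 0)
  q <- quantify_sample(preset_sample("t_dicoccum_wholegrain", 5), noise_sigma = 0)
  expect_equal(q$c_mg_per_kg / q$c_mmol_per_kg, 390)
})

test_that("the flagged inconsistent table rows are excluded from exact conversion", {
  tab <- published_presets()
  flagged <- tab[!is.na(tab$mmol_per_kg_printed) & !tab$conversion_exact, ]
  expect_setequal(flagged$preset, c("t_aestivum_wholegrain", "t_dicoccum_grain"))
})

test_that("S/N follows its height convention and scales with analyte amount", {
  sp <- make_pair_spectrum(5e-4)
  expect_identical(snr(sp), Inf)   # zero-noise sentinel
  expect_error(snr(sp, noise_window = c(6.05, 5.95)), "overlapping_windows")

  s1 <- sample_spec("a", 100, seed = 1)
  s2 <- sample_spec("b", 200, seed = 1)
  p <- small_acq()
  ratios <- vapply(1:20, function(seed) {
    quantify_sample(s2, p, seed = seed)$snr /
      quantify_sample(s1, p, seed = seed + 900)$snr
  }, numeric(1))
  expect_rel_equal(mean(ratios), 2, 0.10)

  # determinism: identical seed gives identical S/N
  q1 <- quantify_sample(s1, p, seed = 5)
  q2 <- quantify_sample(s1, p, seed = 5)
  expect_identical(q1$snr, q2$snr)
})

test_that("detection calls use inclusive S/N thresholds", {
  expect_equal(detection_call(10, 2.9), "nd")
  expect_equal(detection_call(10, 3.0), "below_loq")
  expect_equal(detection_call(50, 9.99), "below_loq")
  expect_equal(detection_call(50, 10.0), "quantified")
  expect_error(detection_call(10, -1), "invalid_snr")
})

test_that("an ARS-free white flour sample is reported as not detected", {
  q <- quantify_sample(preset_sample("t_aestivum_white", seed = 21))
  expect_equal(q$status, "nd")
  expect_lt(q$snr, 3)
  report <- quantify_report(list(preset_sample("t_aestivum_white", seed = 21)))
  expect_true(is.na(report$c_mg_per_kg))
  expect_equal(report$status, "nd")
})

test_that("integration is window-local against a nearby matrix peak", {
  s <- preset_sample("t_monococcum_wholegrain", seed = 9)
  q_clean <- quantify_sample(s, noise_sigma = 0)
  q_adv <- quantify_sample(s, noise_sigma = 0, adversarial = TRUE)
  expect_lt(abs(q_adv$i_ars / q_clean$i_ars - 1), 0.005)
})

test_that("report rounding follows the reporting convention of the assay", {
  r <- report_rounding(455.7, 1.168)
  expect_identical(r$c_mg_per_kg, 456)
  expect_identical(r$c_mmol_per_kg, 1.17)
})
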