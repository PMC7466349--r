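test_that("per-cycle extraction follows the single-pool geometric series", {
  s <- sample_spec("test flour", 638, seed = 1)
  expect_equal(extract(s, 1)$fraction, 0.96)
  expect_equal(extract(s, 2)$fraction, 0.96 * 0.04)
  expect_equal(extract(s, 2)$fraction, 0.0384)

  exhaustive <- sample_spec("x", 100, extraction_efficiency = 1, seed = 1)
  expect_equal(extract(exhaustive, 2)$fraction, 0)
  expect_equal(extract(exhaustive, 5)$fraction, 0)

  # fractions are monotone non-increasing and sum to at most 1
  fr <- vapply(1:12, function(k) extract(s, k)$fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_lte(sum(fr), 1)
  expect_gt(sum(fr), 0.999)  # geometric series converges to the full pool
})

test_that("non-physical extraction efficiencies are rejected", {
  expect_error(sample_spec("x", 100, extraction_efficiency = 0, seed = 1),
               "invalid_sample_spec")
  expect_error(sample_spec("x", 100, extraction_efficiency = 1.2, seed = 1),
               "invalid_sample_spec")
  s <- sample_spec("x", 100, seed = 1)
  s$extraction_efficiency <- -0.5   # corrupt after construction
  expect_error(extract(s, 1), "invalid_efficiency")
  expect_error(extract(s, 0), "invalid_cycle")
  expect_error(sample_spec("x", 100), "seed is mandatory")
})

test_that("amount in the analyzed portion follows mg/Kg x mass / MW", {
  expect_equal(ars_constants()$mw_avg, (376 + 404) / 2)
  s <- sample_spec("T. monococcum", 638, sample_mass = 330, seed = 1)
  expect_equal(amount_from_concentration(s), 638 * 330e-6 / 390)
  expect_equal(amount_from_concentration(s), 5.398e-4, tolerance = 1e-4)
  white <- sample_spec("white flour", 0, seed = 1)
  expect_equal(amount_from_concentration(white), 0)
  expect_error(amount_from_concentration(s, mw_avg = -1), "invalid_mw")
})

test_that("FID synthesis is deterministic under a fixed seed and seed-sensitive", {
  r <- list(resonance(6.0, 3L, 1e-4), resonance(9.79, 1L, 2.7e-3))
  a <- synthesize_fid(r, noise_sigma = 1e-4, seed = 42)
  b <- synthesize_fid(r, noise_sigma = 1e-4, seed = 42)
  expect_identical(a$data, b$data)
  c <- synthesize_fid(r, noise_sigma = 1e-4, seed = 43)
  expect_false(identical(a$data, c$data))
  expect_identical(a$params, c$params)
  expect_error(synthesize_fid(r, noise_sigma = 0), "seed is mandatory")
})

test_that("resonances outside the sweep window are rejected, not aliased", {
  p <- acq_params()
  win <- sweep_window_ppm(p)
  expect_error(
    synthesize_fid(list(resonance(win[1] + 0.5, 1L, 1e-3)), p, seed = 1),
    "resonance_outside_sweep")
  expect_error(
    synthesize_fid(list(resonance(win[2] - 0.5, 1L, 1e-3)), p, seed = 1),
    "resonance_outside_sweep")
})

test_that("processed peak integral is proportional to protons x amount", {
  area1 <- window_integral(single_line_spectrum(amount = 1e-3), c(6.25, 5.75))
  area2 <- window_integral(single_line_spectrum(amount = 2e-3), c(6.25, 5.75))
  area6 <- window_integral(single_line_spectrum(amount = 1e-3, n_protons = 3L),
                           c(6.25, 5.75))
  expect_rel_equal(area2 / area1, 2, 0.005)
  expect_rel_equal(area6 / area1, 3, 0.005)
  # absolute scale agrees with the analytic one-sided Lorentzian area A/2
  A <- 1e-3 * saturation_factor(10, acq_params()$acquisition_time, 1000) * 16
  expect_rel_equal(area1, A / 2, 0.005)
})

test_that("integral ratios follow the closed-form saturation factors across d1", {
  aq <- acq_params()$acquisition_time
  s <- sample_spec("x", 638, seed = 7)
  ratio_at <- function(d1) {
    p <- acq_params(relaxation_delay = d1)
    fid <- synthesize_fid(extract_resonances(s), p, noise_sigma = 0, seed = 7)
    spec <- process_fid(fid, phase_with = phase_params(0, 0))
    unname(integrate_spectrum(spec)[["ars"]])
  }
  analytic <- function(d1) {
    amt <- amount_from_concentration(s)
    3 * amt * saturation_factor(d1, aq, 1.2) /
      (0.00270 * saturation_factor(d1, aq, 2.5))
  }
  for (d1 in c(2, 10, 20)) {
    expect_rel_equal(ratio_at(d1), analytic(d1), 0.005)
  }
  # the d1 = 10 -> 20 change matches the saturation-factor arithmetic
  sim_change <- ratio_at(20) / ratio_at(10) - 1
  ana_change <- analytic(20) / analytic(10) - 1
  expect_lt(abs(sim_change - ana_change), 0.001)
})

test_that("spectral S/N grows as sqrt(n_scans)", {
  s <- sample_spec("x", 200, seed = 1)
  p16 <- small_acq(n_scans = 16L)
  p32 <- small_acq(n_scans = 32L)
  ratios <- vapply(1:20, function(seed) {
    q16 <- quantify_sample(s, p16, noise_sigma = 5.7e-4, seed = seed)
    q32 <- quantify_sample(s, p32, noise_sigma = 5.7e-4, seed = seed + 500)
    q32$snr / q16$snr
  }, numeric(1))
  expect_rel_equal(mean(ratios), sqrt(2), 0.10)
})

test_that("a noise-free synthetic sample recovers its concentration within 1%", {
  s <- preset_sample("t_monococcum_wholegrain", seed = 11)
  q <- quantify_sample(s, noise_sigma = 0)
  expect_rel_equal(q$c_mg_per_kg, 638, 0.01)
  expect_equal(q$status, "quantified")
})

test_that("sample manifests round-trip through CSV", {
  samples <- list(preset_sample("t_monococcum_wholegrain", seed = 1),
                  preset_sample("t_aestivum_white", seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(samples, path)
  back <- read_manifest(path)
  expect_equal(back, samples)
})

test_that("unknown presets are rejected with the list of valid names", {
  expect_error(preset_sample("no_such_flour", seed = 1), "unknown_preset")
  expect_error(preset_sample("no_such_flour", seed = 1),
               "t_monococcum_wholegrain")
})
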