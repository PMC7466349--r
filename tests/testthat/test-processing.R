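test_that("apodization broadens lines by lb without changing areas", {
  fid <- single_line_fid()

  # lb = 0 is the identity
  expect_identical(apodize(fid, 0)$data, fid$data)
  expect_error(apodize(fid, -0.1), "invalid_line_broadening")

  sp0 <- fourier_transform(zero_fill(apodize(fid, 0), 2))
  sp3 <- fourier_transform(zero_fill(apodize(fid, 0.3), 2))
  # natural width 1.0 Hz (t2 = 1/pi) + 0.3 Hz lb
  expect_rel_equal(fwhm_hz(sp0, c(6.3, 5.7)), 1.0, 0.05)
  expect_rel_equal(fwhm_hz(sp3, c(6.3, 5.7)), 1.3, 0.05)
  # peak area is invariant under apodization
  a0 <- window_integral(sp0, c(6.5, 5.5))
  a3 <- window_integral(sp3, c(6.5, 5.5))
  expect_lt(abs(a3 / a0 - 1), 0.001)
})

test_that("zero filling interpolates without changing peak areas", {
  fid <- apodize(single_line_fid(), 0.3)
  expect_identical(zero_fill(fid, 1)$data, fid$data)
  expect_equal(length(zero_fill(fid, 2)$data), 2 * length(fid$data))
  expect_error(zero_fill(fid, 3), "invalid_zero_fill")
  expect_error(zero_fill(fid, 0), "invalid_zero_fill")

  a1 <- window_integral(fourier_transform(fid), c(6.5, 5.5))
  a2 <- window_integral(fourier_transform(zero_fill(fid, 2)), c(6.5, 5.5))
  expect_lt(abs(a2 / a1 - 1), 0.001)
})

test_that("the Fourier transform places and scales peaks correctly", {
  sp <- single_line_spectrum(shift = 6.00)
  peak_ppm <- sp$ppm[which.max(sp$real)]
  expect_lt(abs(peak_ppm - 6.00),
            digital_resolution(sp) / sp$params$spectrometer_freq)

  # two resonances: height ratio = (n_protons x amount x saturation) ratio
  aq <- acq_params()$acquisition_time
  fid <- synthesize_fid(list(
    resonance(6.0, 3L, 1e-3, t1 = 1.2),
    resonance(9.79, 1L, 2e-3, t1 = 2.5)), noise_sigma = 0, seed = 1)
  sp2 <- fourier_transform(zero_fill(apodize(fid, 0.3), 2))
  h_ars <- max(sp2$real[sp2$ppm < 6.3 & sp2$ppm > 5.7])
  h_is <- max(sp2$real[sp2$ppm < 10.1 & sp2$ppm > 9.5])
  expected <- (3 * 1e-3 * saturation_factor(10, aq, 1.2)) /
    (1 * 2e-3 * saturation_factor(10, aq, 2.5))
  expect_rel_equal(h_ars / h_is, expected, 0.01)

  # degenerate inputs
  zero_fid <- synthesize_fid(list(resonance(6, 1L, 0)), noise_sigma = 0, seed = 1)
  expect_true(all(fourier_transform(zero_fid)$real == 0))
  empty <- zero_fid; empty$data <- complex(0)
  expect_error(fourier_transform(empty), "empty_fid")
})

test_that("digital resolution equals 1/acquisition_time before zero filling", {
  sp <- single_line_spectrum(zero_fill_factor = 1L)
  expect_rel_equal(digital_resolution(sp), 1 / acq_params()$acquisition_time,
                   0.01)
})

test_that("automatic phasing recovers a deliberate zero-order error", {
  sp <- single_line_spectrum(amount = 1e-3)
  ref_area <- window_integral(sp, c(6.25, 5.75))

  rotated <- phase(sp, phase_params(30, 0))
  tilted_area <- window_integral(rotated, c(6.25, 5.75))
  expect_lt(tilted_area, ref_area)   # dispersion leakage reduces the area

  fixed <- phase(rotated, "auto")
  fit <- attr(fixed, "phase_fit")
  expect_lt(abs(fit$zero_order - (-30)), 1)
  expect_true(fit$converged)
  expect_rel_equal(window_integral(fixed, c(6.25, 5.75)), ref_area, 0.005)
})

test_that("manual phasing with zero angles is the identity", {
  sp <- single_line_spectrum()
  out <- phase(sp, phase_params(0, 0))
  expect_equal(out$real, sp$real)
  expect_equal(out$imag, sp$imag)
  expect_error(phase_params(200, 0), "invalid_phase")
  expect_error(phase(sp, "garbage"), "invalid_phase")
})

test_that("polynomial baseline correction removes injected distortions", {
  sp <- single_line_spectrum()
  ref_area <- window_integral(sp, c(6.25, 5.75))

  # flat baseline: the correction itself is negligible
  flat <- baseline_correct(sp)
  expect_lt(max(abs(flat$real - sp$real)), 1e-5 * max(sp$real))

  # linear tilt across the spectrum is removed
  tilted <- sp
  tilt <- seq(-1, 1, length.out = length(sp$real)) * max(sp$real) * 0.05
  tilted$real <- tilted$real + tilt
  fixed <- baseline_correct(tilted)
  expect_rel_equal(window_integral(fixed, c(6.25, 5.75)), ref_area, 0.01)

  # degree 0 removes a constant offset (up to the far Lorentzian tails
  # present in the anchor windows)
  shifted <- sp
  shifted$real <- shifted$real + 0.123
  fixed0 <- baseline_correct(shifted, degree = 0)
  expect_lt(max(abs(fixed0$real - sp$real)), 1e-5 * max(sp$real))

  expect_error(baseline_correct(sp, anchors = list(c(6.05, 5.95))),
               "anchor_overlaps_integration_window")
  expect_error(baseline_correct(sp, method = "spline"),
               "invalid_baseline_method")
})

test_that("ppm calibration re-references the axis on the solvent line", {
  fid <- synthesize_fid(list(resonance(2.50, 1L, 0.02, t1 = 1.9)),
                        noise_sigma = 0, seed = 1)
  sp <- fourier_transform(zero_fill(apodize(fid, 0.3), 2))

  cal <- calibrate_ppm(sp)
  expect_lt(abs(cal$ppm[which.max(cal$real)] - 2.50), 1e-9)

  off <- sp
  off$ppm <- off$ppm + 0.05   # mis-referenced axis
  fixed <- calibrate_ppm(off)
  step <- digital_resolution(sp) / sp$params$spectrometer_freq
  expect_lt(abs(fixed$ppm[which.max(fixed$real)] - 2.50), step)

  expect_error(calibrate_ppm(sp, window = c(8.2, 7.8)), "no_reference_peak")
})

test_that("every processing step appends exactly one log entry", {
  fid <- single_line_fid(shift = 2.50, amount = 0.02, t1 = 1.9)
  n0 <- length(fid$processing_log)
  fid <- apodize(fid, 0.3);        expect_length(fid$processing_log, n0 + 1)
  fid <- zero_fill(fid, 2);        expect_length(fid$processing_log, n0 + 2)
  sp <- fourier_transform(fid);    expect_length(sp$processing_log, n0 + 3)
  sp <- phase(sp, phase_params(0, 0)); expect_length(sp$processing_log, n0 + 4)
  sp <- baseline_correct(sp);      expect_length(sp$processing_log, n0 + 5)
  sp <- calibrate_ppm(sp);         expect_length(sp$processing_log, n0 + 6)
  expect_match(sp$processing_log[n0 + 1], "apodize")
  expect_match(sp$processing_log[n0 + 6], "calibrate_ppm")
})

test_that("the full chain preserves peak areas on noise-free input", {
  fid <- single_line_fid(amount = 1e-3)
  sp <- process_fid(fid, calibrate = FALSE)
  A <- 1e-3 * saturation_factor(10, acq_params()$acquisition_time, 1000) * 16
  expect_rel_equal(window_integral(sp, c(6.25, 5.75)), A / 2, 0.01)
})
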