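# shared fixtures: all built in code, no stored data

# a shorter acquisition (8 K real+imaginary points, same sweep) for
# Monte-Carlo loops where the printed acquisition constants don't matter
small_acq <- function(td = 8192L, ...) {
  acq_params(td_points = td, ...)
}

# single isolated line at 6.00 ppm, effectively fully relaxed
single_line_fid <- function(amount = 1e-3, n_protons = 1L, t2 = 1 / pi,
                            params = acq_params(), noise_sigma = 0,
                            seed = 1, shift = 6.00, t1 = 1000) {
  synthesize_fid(list(resonance(shift, n_protons, amount, t2 = t2, t1 = t1)),
                 params, noise_sigma = noise_sigma, seed = seed)
}

# noise-free absorption spectrum of a single line, no phasing/baseline needed
single_line_spectrum <- function(..., line_broadening = 0.3,
                                 zero_fill_factor = 2L) {
  fid <- single_line_fid(...)
  fourier_transform(zero_fill(apodize(fid, line_broadening), zero_fill_factor))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
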