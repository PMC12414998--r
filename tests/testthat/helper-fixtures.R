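# Fixture builders shared across tests; everything is generated in code.

make_test_axis <- function(lo = 200, hi = 18000, by = 200) {
  freq_axis(seq(lo, hi, by = by))
}

make_test_spectra <- function(n_dir = 3, axis = make_test_axis(), seed = 42) {
  set.seed(seed)
  nf <- length(axis$frequencies)
  m <- array(stats::rnorm(n_dir * 2 * nf, 0, 5), c(n_dir, 2, nf))
  magnitude_spectra(m, axis,
                    data.frame(lateral = seq(-30, 30, length.out = n_dir),
                               polar = seq(0, 180, length.out = n_dir)))
}

test_band <- function(C = 1) contrast_spec(C, 1000, 16000)

# weighted in-band mean of one spectrum
weighted_inband_mean <- function(specs, w, d, e) {
  wn <- w$weights / sum(w$weights)
  sum(wn * specs$magnitudes[d, e, w$idx])
}

small_config <- function(n_subjects = 4, ...) {
  synthetic_config(n_subjects = n_subjects, n_blocks = 2,
                   trials_per_block = 40,
                   erp = list(n_channels = 16, effect_channels = NULL,
                              effect_window = c(0.08, 0.17), effect_uv = 1,
                              noise_sd = 1, spatial_decay = 0.04,
                              trials_per_condition = 8, fs = 100,
                              tmin = -0.1, tmax = 0.5),
                   ...)
}

test_layout <- function(n = 16) loomingbias:::synthetic_cap_layout(n)
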