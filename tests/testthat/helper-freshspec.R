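# shared fixtures, built in code at load time

default_params <- make_aging_params("sablefish", 1)

# a small noisy multi-mode study used by several classification tests
small_study <- function(seed = 7, vpfd = 40, noise_sd = 0.01,
                        days = c(1, 3, 7, 9, 11)) {
  simulate_study(list(voxels_per_fillet_day = vpfd, days = days,
                      noise_sd = noise_sd), seed = seed)
}

# two-Gaussian fluorescence spectrum with known parameters
two_peak_spectrum <- function(wl, dl, ratio, p1_c = 452.6, p1_fwhm = 40,
                              p2_fwhm = 110, baseline = 0.03, noise = 0) {
  s <- baseline +
    exp(-0.5 * ((wl - p1_c) / (p1_fwhm / 2.3548))^2) +
    (1 / ratio) * exp(-0.5 * ((wl - p1_c - dl) / (p2_fwhm / 2.3548))^2)
  if (noise > 0) s <- s + rnorm(length(wl), 0, noise * max(s))
  s
}

# upper edge of the permutation-null accuracy band (binomial, level 0.999)
null_band_upper <- function(n_test, n_classes, level = 0.999) {
  qbinom(level, n_test, 1 / n_classes) / n_test
}
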