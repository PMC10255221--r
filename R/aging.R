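FILLET_REGIONS <- c("head_top", "head_bottom", "tail_top", "tail_bottom")

#' Build a species-specific spectral aging model
#'
#' Encodes the aging signatures the pipeline is designed to detect.
#' Fluorescence spectra carry a two-peak structure: a primary emission peak
#' P1 whose centre stays fixed near 452.6 nm as the fillet ages, and a
#' subsidiary peak P2 whose separation from P1 (delta lambda) shrinks with
#' day while the P1/P2 height ratio grows. Reflectance modes (VisNIR, SWIR)
#' carry a smooth base reflectance plus day-weighted drift components.
#' Catabolite flow (IMP -> inosine -> hypoxanthine) is parameterised by two
#' first-order rate constants.
#'
#' The model is fully deterministic for a given `(species, seed)` pair:
#' species-dependent components (base reflectance shape, drift band weights)
#' are drawn from a stream seeded by both.
#'
#' @param species Species label, e.g. `"sablefish"`.
#' @param seed Integer seed.
#' @param delta_lambda_day1 Peak separation P2 - P1 on day 1, nm.
#' @param delta_lambda_shrink_total Total shrink of the separation over days
#'   1 to 11, nm. Default 20 nm (the strongest observed regional trend).
#' @param ratio_day1 P1/P2 height ratio on day 1.
#' @param ratio_growth_per_day Ratio increase per day.
#' @param noise_sd Relative additive noise level (fraction of peak signal).
#' @param cutoff_height Relative height of the short-wavelength cut-off bump
#'   emulating incomplete rejection of the excitation band; 0 disables it.
#' @return An object of class `aging_model`.
#' @export
make_aging_params <- function(species, seed,
                              delta_lambda_day1 = 85,
                              delta_lambda_shrink_total = 20,
                              ratio_day1 = 0.8,
                              ratio_growth_per_day = 0.06,
                              noise_sd = 0.01,
                              cutoff_height = 0.08) {
  if (!is.character(species) || length(species) != 1L)
    stop_f("`species` must be a single string")
  assert_scalar_number(seed, "seed")
  sub_seed <- (as.integer(seed) %% 100000L) * 20011L + string_seed(species)
  sub_seed <- sub_seed %% 2147480009

  model <- with_seed(sub_seed, {
    p2_fwhm_range <- c(103.9, 115.9)
    list(
      species = species,
      seed = as.integer(seed),
      p1_center = 452.6,
      p1_fwhm = 40 + runif(1, -4, 4),
      p2_center_day1 = 452.6 + delta_lambda_day1,
      delta_lambda_day1 = delta_lambda_day1,
      delta_lambda_shrink_total = delta_lambda_shrink_total,
      ratio_day1 = ratio_day1,
      ratio_growth_per_day = ratio_growth_per_day,
      p2_fwhm_range = p2_fwhm_range,
      p2_fwhm = runif(1, p2_fwhm_range[1L], p2_fwhm_range[2L]),
      cutoff_height = cutoff_height,
      reflectance_base = list(
        VISNIR = smooth_band_profile(mode_wavelengths("VISNIR"), level = 0.35),
        SWIR   = smooth_band_profile(mode_wavelengths("SWIR"), level = 0.30)),
      reflectance_drift_coeffs = list(
        VISNIR = smooth_band_profile(mode_wavelengths("VISNIR"),
                                     level = 0, amplitude = 0.12),
        SWIR   = smooth_band_profile(mode_wavelengths("SWIR"),
                                     level = 0, amplitude = 0.12)),
      noise_sd = noise_sd,
      region_gradients = stats::setNames(
        1 + runif(length(FILLET_REGIONS), -0.06, 0.06), FILLET_REGIONS)
    )
  })
  structure(model, class = "aging_model")
}

# species-dependent smooth spectral profile: a constant level plus a few
# broad Gaussian bumps with random centres/signs
smooth_band_profile <- function(wl, level, amplitude = 0.15, n_bumps = 3L) {
  centers <- runif(n_bumps, min(wl), max(wl))
  widths <- runif(n_bumps, 0.12, 0.30) * diff(range(wl))
  heights <- runif(n_bumps, 0.3, 1) * sample(c(-1, 1), n_bumps, TRUE)
  prof <- rep(level, length(wl))
  for (j in seq_len(n_bumps))
    prof <- prof + amplitude * heights[j] * exp(-0.5 * ((wl - centers[j]) / widths[j])^2)
  prof
}

#' @export
print.aging_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<aging_model> species=%s seed=%d\n",
    "  P1 %.1f nm (FWHM %.1f), delta-lambda day1 %.1f nm shrinking %.1f nm by day 11\n",
    "  P1/P2 day1 %.2f growing %.3f/day; noise sd %.3f\n"),
    x$species, x$seed, x$p1_center, x$p1_fwhm, x$delta_lambda_day1,
    x$delta_lambda_shrink_total, x$ratio_day1, x$ratio_growth_per_day,
    x$noise_sd))
  invisible(x)
}

# day-dependent aging features (days 1..11); linear trends
aging_delta_lambda <- function(model, day) {
  model$delta_lambda_day1 - model$delta_lambda_shrink_total * (day - 1) / 10
}

aging_ratio <- function(model, day) {
  model$ratio_day1 + model$ratio_growth_per_day * (day - 1)
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
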