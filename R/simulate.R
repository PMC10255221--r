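STUDY_DAYS <- c(1, 3, 5, 7, 9, 11)

#' Simulate one spectrum of a given mode, day and fillet region
#'
#' Fluorescence (`FL`) spectra are a linear baseline plus two Gaussian
#' emission components (P1 fixed near 452.6 nm, P2 at P1 + delta-lambda(day))
#' plus an optional short-wavelength cut-off bump, with additive Gaussian
#' noise. Reflectance modes return the model's smooth base reflectance scaled
#' by day-weighted drift components plus noise. The two-Gaussian form makes
#' the downstream peak deconvolution exactly identifiable on noise-free data.
#'
#' @param mode Spectral mode tag.
#' @param day Measurement day (1--11).
#' @param region Fillet region, one of `"head_top"`, `"head_bottom"`,
#'   `"tail_top"`, `"tail_bottom"`.
#' @param params An [make_aging_params()] model.
#' @param noise_sd Relative noise level; defaults to the model's; 0 gives a
#'   noise-free spectrum. Draws come from the ambient RNG stream.
#' @return Numeric intensity vector, one value per band of the mode.
#' @export
simulate_spectrum <- function(mode, day, region = "tail_bottom", params,
                              noise_sd = NULL) {
  mode <- match_mode(mode)
  if (!inherits(params, "aging_model")) stop_f("`params` must be an aging_model")
  if (!region %in% FILLET_REGIONS)
    stop_f("unknown fillet region '%s'", region)
  if (day < 0 || day > 14) stop_f("`day` outside the study range")
  noise_sd <- noise_sd %||% params$noise_sd
  wl <- mode_wavelengths(mode)
  clean <- clean_spectrum(mode, day, region, params, wl)
  if (noise_sd > 0)
    clean <- clean + stats::rnorm(length(wl), 0, noise_sd * max(abs(clean)))
  clean
}

clean_spectrum <- function(mode, day, region, params, wl) {
  g <- params$region_gradients[[region]]
  if (mode == "FL") {
    p1_h <- 1
    p2_h <- p1_h / aging_ratio(params, day)
    p2_c <- params$p1_center + aging_delta_lambda(params, day)
    base <- 0.03 + 0.00005 * (wl - min(wl)) # shallow linear baseline
    sig <- p1_h * exp(-0.5 * ((wl - params$p1_center) / fwhm_to_sd(params$p1_fwhm))^2) +
      p2_h * exp(-0.5 * ((wl - p2_c) / fwhm_to_sd(params$p2_fwhm))^2)
    if (params$cutoff_height > 0)
      sig <- sig + params$cutoff_height *
        exp(-0.5 * ((wl - (min(wl) + 6)) / 5)^2)
    g * (base + sig)
  } else {
    base <- params$reflectance_base[[mode]]
    drift <- params$reflectance_drift_coeffs[[mode]]
    f <- (day - 1) / 10
    # linear + mild quadratic day weighting gives each day a distinct shape
    refl <- base * (1 + f * drift + 0.4 * f^2 * rev(drift))
    pmin(pmax(g * refl, 0.001), 1)
  }
}

#' Simulate a full hypercube with fillet foreground and artifacts
#'
#' Builds a cube with an elliptical fillet-shaped foreground split into four
#' regions (head/tail x top/bottom), a dark background, optional saturated
#' pixel blocks aligned to 10x10 voxel tiles (so saturation maps exactly onto
#' whole voxels), and white/dark reference frames for reflectance modes.
#' For reflectance modes the stored raw counts are
#' `reflectance * (white - dark) + dark`, so white/dark calibration recovers
#' the underlying reflectance.
#'
#' @param mode,day,params As in [simulate_spectrum()].
#' @param seed Optional seed making the cube reproducible.
#' @param saturation_fraction Fraction of foreground pixels to clip at the
#'   saturation ceiling, in `[0, 1)`; rounded to whole 10x10 tiles.
#' @param background Include a connected non-fillet background region
#'   (always present; `FALSE` makes the whole image fillet).
#' @param rows,cols Spatial size; default the instrument geometry of `mode`.
#' @param noise_sd Relative noise; defaults to the model's.
#' @return A [hypercube()] with attributes `foreground` (logical rows x cols
#'   ground-truth footprint) and `saturated_tiles` (data.frame of planted
#'   10x10 block coordinates).
#' @export
simulate_hypercube <- function(mode, day, params, seed = NULL,
                               saturation_fraction = 0, background = TRUE,
                               rows = NULL, cols = NULL, noise_sd = NULL) {
  mode <- match_mode(mode)
  if (saturation_fraction < 0 || saturation_fraction >= 1)
    stop_f("`saturation_fraction` must be in [0, 1)")
  geom <- mode_geometry(mode)
  rows <- as.integer(rows %||% geom[1L])
  cols <- as.integer(cols %||% geom[2L])
  wl <- mode_wavelengths(mode)
  nb <- length(wl)
  noise_sd <- noise_sd %||% params$noise_sd

  with_seed(seed, {
    fg <- if (background) elliptical_footprint(rows, cols) else
      matrix(TRUE, rows, cols)
    region_map <- region_labels(rows, cols)

    # per-region clean spectra
    reg_spec <- vapply(FILLET_REGIONS, function(r)
      clean_spectrum(mode, day, r, params, wl), numeric(nb))

    is_refl <- mode != "FL"
    if (is_refl) {
      dark <- matrix(0.04 + stats::rnorm(rows * nb, 0, 0.002), rows, nb)
      white <- matrix(0.9, rows, nb) +
        outer(0.05 * sin(seq(0, pi, length.out = rows)), rep(1, nb)) +
        stats::rnorm(rows * nb, 0, 0.002)
    } else {
      dark <- NULL; white <- NULL
    }

    data <- array(0, dim = c(rows, cols, nb))
    # smooth per-pixel multiplicative heterogeneity field
    het <- outer(1 + 0.03 * sin(seq(0, 3 * pi, length.out = rows)),
                 1 + 0.03 * cos(seq(0, 2 * pi, length.out = cols)))
    fgv <- which(fg)
    bgv <- which(!fg)
    for (b in seq_len(nb)) {
      plane <- matrix(0, rows, cols)
      sig <- reg_spec[b, region_map[fgv]] * het[fgv] *
        (1 + stats::rnorm(length(fgv), 0, noise_sd))
      if (is_refl) {
        r_idx <- ((fgv - 1L) %% rows) + 1L
        plane[fgv] <- pmin(pmax(sig, 0), 1.05) * (white[r_idx, b] - dark[r_idx, b]) +
          dark[r_idx, b]
        if (length(bgv)) {
          r_bg <- ((bgv - 1L) %% rows) + 1L
          plane[bgv] <- dark[r_bg, b] + abs(stats::rnorm(length(bgv), 0.01, 0.003))
        }
      } else {
        plane[fgv] <- pmax(sig, 0)
        if (length(bgv))
          plane[bgv] <- abs(stats::rnorm(length(bgv), 0.005, 0.002))
      }
      data[, , b] <- plane
    }

    ceiling_val <- if (is_refl) 1.2 else 4 * max(reg_spec)
    sat_tiles <- data.frame(block_row = integer(0), block_col = integer(0))
    if (saturation_fraction > 0) {
      # whole 10x10 tiles fully inside the foreground
      tiles <- complete_tiles(fg, block = 10L, min_inside = 1)
      n_fg <- length(fgv)
      n_tiles <- max(1L, round(saturation_fraction * n_fg / 100))
      n_tiles <- min(n_tiles, nrow(tiles))
      pick <- tiles[sample.int(nrow(tiles), n_tiles), , drop = FALSE]
      for (t in seq_len(nrow(pick))) {
        ri <- (pick$block_row[t] - 1L) * 10L + seq_len(10L)
        ci <- (pick$block_col[t] - 1L) * 10L + seq_len(10L)
        data[ri, ci, ] <- ceiling_val
      }
      sat_tiles <- pick
    }
    data[data > ceiling_val] <- ceiling_val

    cube <- hypercube(data, wl, mode,
                      exposure_ms = if (mode == "SWIR") 6 else 50,
                      white_frame = white, dark_frame = dark,
                      saturation_ceiling = ceiling_val)
    attr(cube, "foreground") <- fg
    attr(cube, "saturated_tiles") <- sat_tiles
    cube
  })
}

elliptical_footprint <- function(rows, cols) {
  r0 <- (rows + 1) / 2; c0 <- (cols + 1) / 2
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((rr - r0) / (0.42 * rows))^2 + ((cc - c0) / (0.40 * cols))^2 <= 1
}

region_labels <- function(rows, cols) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  m <- matrix("tail_bottom", rows, cols)
  m[rr <= rows / 2 & cc <= cols / 2] <- "head_top"
  m[rr <= rows / 2 & cc > cols / 2] <- "tail_top"
  m[rr > rows / 2 & cc <= cols / 2] <- "head_bottom"
  m
}

# tiles of size block x block fully contained in the image whose in-mask
# fraction is >= min_inside
complete_tiles <- function(mask, block, min_inside) {
  nr <- nrow(mask) %/% block
  nc <- ncol(mask) %/% block
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- (i - 1L) * block + seq_len(block)
    ci <- (j - 1L) * block + seq_len(block)
    if (mean(mask[ri, ci]) >= min_inside)
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(block_row = integer(0), block_col = integer(0)))
  m <- do.call(rbind, out)
  data.frame(block_row = m[, 1L], block_col = m[, 2L])
}

#' Closed-form sequential first-order catabolite kinetics
#'
#' Post-mortem nucleotide degradation follows the pathway
#' IMP -> inosine -> hypoxanthine with first-order rate constants `k1`, `k2`
#' (per day). The closed-form solution of the two-step ODE is returned; the
#' three components always sum to `initial_imp` (closed pathway).
#'
#' @param day Days post-mortem (>= 0).
#' @param k1,k2 Rate constants in 1/day (> 0). Near-equal rates are handled
#'   by the limiting form.
#' @param initial_imp Initial IMP amount (fraction or %).
#' @return Object of class `catabolites_profile` with fields `imp`,
#'   `inosine`, `hx`, `day`, `k1`, `k2`.
#' @export
simulate_catabolites <- function(day, k1 = 0.35, k2 = 0.12, initial_imp = 1) {
  assert_scalar_number(day, "day")
  if (day < 0) stop_f("`day` must be non-negative")
  if (k1 <= 0 || k2 <= 0) stop_f("rate constants must be positive")
  imp <- initial_imp * exp(-k1 * day)
  ino <- if (abs(k1 - k2) < 1e-10) {
    initial_imp * k1 * day * exp(-k1 * day)
  } else {
    initial_imp * k1 / (k2 - k1) * (exp(-k1 * day) - exp(-k2 * day))
  }
  hx <- initial_imp - imp - ino
  structure(list(imp = imp, inosine = ino, hx = hx,
                 day = day, k1 = k1, k2 = k2),
            class = "catabolites_profile")
}

#' Simulate a full multi-mode study
#'
#' Generates labelled voxel tables for each spectral mode, emulating the
#' study design: a set of fillets imaged on alternate days, several hundred
#' voxel spectra per fillet per day, four fillet regions, shared fillet
#' identities across modes. Voxels are index-aligned across modes (same
#' fillet/day/region sequence), which makes voxel-level fusion exact on
#' synthetic data.
#'
#' @param config List with elements `species` (default `"sablefish"`),
#'   `days` (default `c(1,3,5,7,9,11)`; use `drop_day5 = TRUE` to mirror the
#'   sablefish exclusion), `n_fillets` (default 1), `voxels_per_fillet_day`
#'   (default 100), `noise_sd` (default the model's), `modes` (default all
#'   three).
#' @param seed Integer seed; identical `(config, seed)` give bit-identical
#'   datasets.
#' @return Object of class `multimode_dataset`: list with `voxel_tables`
#'   (one [voxel_table] per mode), `day_classes`, `species`, `seed`,
#'   `params`.
#' @export
simulate_study <- function(config = list(), seed = 1) {
  species <- config$species %||% "sablefish"
  days <- config$days %||% STUDY_DAYS
  if (isTRUE(config$drop_day5)) days <- setdiff(days, 5)
  if (!length(days)) stop_f("`days` must be non-empty")
  n_fillets <- config$n_fillets %||% 1L
  vpfd <- config$voxels_per_fillet_day %||% 100L
  modes <- config$modes %||% c("FL", "VISNIR", "SWIR")
  params <- make_aging_params(species, seed,
                              noise_sd = config$noise_sd %||% 0.01)

  with_seed(seed, {
    design <- expand.grid(voxel = seq_len(vpfd), fillet = seq_len(n_fillets),
                          day = days)
    design$region <- sample(FILLET_REGIONS, nrow(design), replace = TRUE)
    design$jitter <- stats::rnorm(nrow(design), 1, 0.015)

    tables <- lapply(modes, function(m) {
      wl <- mode_wavelengths(m)
      clean <- vapply(FILLET_REGIONS, function(r) {
        vapply(days, function(d) clean_spectrum(m, d, r, params, wl),
               numeric(length(wl)))
      }, matrix(0, length(wl), length(days)))
      # clean: bands x days x regions
      spec <- matrix(0, nrow(design), length(wl))
      for (i in seq_len(nrow(design))) {
        s <- clean[, match(design$day[i], days), match(design$region[i], FILLET_REGIONS)]
        spec[i, ] <- design$jitter[i] * s +
          stats::rnorm(length(wl), 0, params$noise_sd * max(abs(s)))
      }
      new_voxel_table(
        meta = data.frame(
          voxel_id = sprintf("%s_f%d_d%02d_v%04d", m, design$fillet,
                             design$day, design$voxel),
          fillet_id = design$fillet, species = species, day = design$day,
          block_row = ((design$voxel - 1L) %/% 10L) + 1L,
          block_col = ((design$voxel - 1L) %% 10L) + 1L,
          kept = TRUE),
        spectra = spec, wavelengths = wl, mode = m)
    })
    names(tables) <- modes
    structure(list(voxel_tables = tables, day_classes = sort(days),
                   species = species, seed = as.integer(seed),
                   params = params),
              class = "multimode_dataset")
  })
}

#' @export
print.multimode_dataset <- function(x, ...) {
  cat(sprintf("<multimode_dataset> %s, days {%s}, modes: %s\n", x$species,
              paste(x$day_classes, collapse = ","),
              paste(names(x$voxel_tables), collapse = ", ")))
  for (m in names(x$voxel_tables))
    cat(sprintf("  %-6s %d voxels x %d bands\n", m,
                nrow(x$voxel_tables[[m]]),
                length(attr(x$voxel_tables[[m]], "wavelengths"))))
  invisible(x)
}
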