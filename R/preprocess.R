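#' White/dark reflectance calibration
#'
#' Converts raw counts to reflectance with the standard flat-field formula
#' `(raw - dark) / (white - dark)`, element-wise, making spectra comparable
#' across days independently of ambient light. Reference frames default to
#' the ones stored in the cube.
#'
#' @param raw A [hypercube()] in raw counts.
#' @param white,dark Reference frames (rows x bands matrices or full
#'   arrays); default `raw$white_frame` / `raw$dark_frame`.
#' @return A reflectance-unit hypercube (white/dark frames dropped,
#'   saturation ceiling rescaled to 1 + tolerance).
#' @export
calibrate_cube <- function(raw, white = raw$white_frame,
                           dark = raw$dark_frame) {
  if (!inherits(raw, "hypercube")) stop_f("`raw` must be a hypercube")
  if (is.null(white) || is.null(dark))
    stop_f("white and dark reference frames are required")
  d <- dim(raw$data)
  W <- frame_as_cube(white, d)
  D <- frame_as_cube(dark, d)
  denom <- W - D
  if (any(denom <= 0)) {
    bad <- which(apply(denom <= 0, 3, any))
    stop_f("white - dark is not positive at band(s) %s (%.1f nm ...)",
           paste(utils::head(bad, 5), collapse = ", "),
           raw$wavelengths[bad[1L]])
  }
  refl <- (raw$data - D) / denom
  out <- hypercube(refl, raw$wavelengths, raw$mode,
                   exposure_ms = raw$exposure_ms,
                   saturation_ceiling = Inf)
  attr(out, "foreground") <- attr(raw, "foreground")
  attr(out, "saturated_tiles") <- attr(raw, "saturated_tiles")
  out
}

#' Scale intensities to a common exposure time
#'
#' Line-scan acquisitions taken at different exposure times are made
#' comparable by multiplying intensities by
#' `reference_exposure_ms / exposure_ms` (detector response assumed linear
#' in exposure time). The exposure metadata is updated.
#'
#' @param cube A [hypercube()].
#' @param reference_exposure_ms Target exposure in ms (> 0).
#' @export
scale_for_exposure <- function(cube, reference_exposure_ms) {
  if (!inherits(cube, "hypercube")) stop_f("`cube` must be a hypercube")
  assert_scalar_number(reference_exposure_ms, "reference_exposure_ms")
  if (reference_exposure_ms <= 0 || cube$exposure_ms <= 0)
    stop_f("exposure times must be positive")
  f <- reference_exposure_ms / cube$exposure_ms
  out <- cube
  out$data <- cube$data * f
  out$exposure_ms <- reference_exposure_ms
  if (is.finite(cube$saturation_ceiling))
    out$saturation_ceiling <- cube$saturation_ceiling * f
  out
}

#' Build a fillet mask
#'
#' Separates fillet from background by thresholding a summary image --
#' either the across-band mean intensity (`"band-threshold"`) or a single
#' high-contrast reference band (`"reference-band"`) -- at a relative level
#' between the image minimum and maximum, then keeps only the largest
#' connected foreground component.
#'
#' @param cube A [hypercube()].
#' @param strategy `"band-threshold"` or `"reference-band"`.
#' @param threshold Relative threshold in (0, 1).
#' @param band Band index for the reference-band strategy (default the
#'   brightest band).
#' @return Logical rows x cols matrix, `TRUE` on the fillet.
#' @export
build_mask <- function(cube, strategy = c("band-threshold", "reference-band"),
                       threshold = 0.2, band = NULL) {
  if (!inherits(cube, "hypercube")) stop_f("`cube` must be a hypercube")
  strategy <- match.arg(strategy)
  if (threshold <= 0 || threshold >= 1) stop_f("`threshold` must be in (0, 1)")
  img <- if (strategy == "band-threshold") {
    rowMeans(matrix(cube$data, prod(dim(cube$data)[1:2]), dim(cube$data)[3L]))
  } else {
    b <- band %||% which.max(apply(cube$data, 3, stats::median))
    as.vector(cube$data[, , b])
  }
  img <- matrix(img, dim(cube$data)[1L], dim(cube$data)[2L])
  # robust anchors so saturated specks cannot stretch the contrast range
  rng <- stats::quantile(img, c(0.05, 0.90), names = FALSE)
  if (diff(rng) == 0) stop_f("cube has no contrast; empty foreground")
  fg <- img > rng[1L] + threshold * diff(rng)
  if (!any(fg)) stop_f("empty foreground at threshold %.2f", threshold)
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  storage.mode(mask) <- "logical"
  mask
}

#' Spatially average a cube into voxels
#'
#' Resamples the masked image by averaging over `block` x `block` pixel
#' tiles. One voxel row is produced per complete tile at least half of whose
#' pixels lie inside the mask; the voxel spectrum is the mean over the
#' tile's in-mask pixels.
#'
#' @param cube A [hypercube()].
#' @param mask Logical fillet mask matching the cube's spatial shape.
#' @param block Tile side in pixels (default 10).
#' @param fillet_id,species,day Metadata stamped onto the rows.
#' @return A [new_voxel_table()].
#' @export
voxelize <- function(cube, mask, block = 10L, fillet_id = 1L,
                     species = "unknown", day = NA_real_) {
  if (!inherits(cube, "hypercube")) stop_f("`cube` must be a hypercube")
  d <- dim(cube$data)
  if (!is.matrix(mask) || !all(dim(mask) == d[1:2]))
    stop_f("`mask` must match the cube's spatial shape")
  block <- as.integer(block)
  if (block < 1L) stop_f("`block` must be >= 1")
  if (block > d[1L] || block > d[2L]) stop_f("`block` larger than the image")
  tiles <- complete_tiles(mask, block, min_inside = 0.5)
  if (!nrow(tiles)) stop_f("no tile is at least half inside the mask")

  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  spec <- matrix(0, nrow(tiles), d[3L])
  for (t in seq_len(nrow(tiles))) {
    ri <- (tiles$block_row[t] - 1L) * block + seq_len(block)
    ci <- (tiles$block_col[t] - 1L) * block + seq_len(block)
    sub <- mask[ri, ci]
    pix <- as.vector(outer(ri, (ci - 1L) * d[1L], `+`))[as.vector(sub)]
    spec[t, ] <- colMeans(flat[pix, , drop = FALSE])
  }
  meta <- data.frame(
    voxel_id = sprintf("%s_f%s_r%03d_c%03d", cube$mode, fillet_id,
                       tiles$block_row, tiles$block_col),
    fillet_id = fillet_id, species = species, day = day,
    block_row = tiles$block_row, block_col = tiles$block_col, kept = TRUE)
  out <- new_voxel_table(meta, spec, cube$wavelengths, cube$mode)
  attr(out, "block") <- block
  out
}

#' Flag outlier voxels by the >10% / 2-SD rule
#'
#' Per-band mean and standard deviation of pixel intensities are computed
#' over all in-mask fillet pixels. A voxel is excluded (`kept = FALSE`) when,
#' at any wavelength band, strictly more than `frac` of its member pixels
#' deviate from the band mean by more than `k_sd` standard deviations --
#' removing saturated blocks, deep grooves and similar artifacts. The
#' operation is idempotent: flags are recomputed from the cube each call.
#'
#' @param cube The calibrated cube the table was derived from.
#' @param table The [voxelize()] output.
#' @param mask The mask used in voxelization.
#' @param frac Exclusion fraction threshold (strictly greater than; default
#'   0.10).
#' @param k_sd SD multiplier (default 2).
#' @return `table` with the `kept` column updated.
#' @export
flag_outlier_voxels <- function(cube, table, mask, frac = 0.10, k_sd = 2.0) {
  if (frac <= 0 || frac >= 1) stop_f("`frac` must be in (0, 1)")
  if (k_sd <= 0) stop_f("`k_sd` must be positive")
  d <- dim(cube$data)
  block <- attr(table, "block") %||% 10L
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  inmask <- as.vector(mask)
  mu <- colMeans(flat[inmask, , drop = FALSE])
  sdv <- apply(flat[inmask, , drop = FALSE], 2, stats::sd)

  kept <- logical(nrow(table))
  for (t in seq_len(nrow(table))) {
    ri <- (table$block_row[t] - 1L) * block + seq_len(block)
    ci <- (table$block_col[t] - 1L) * block + seq_len(block)
    sub <- mask[ri, ci]
    pix <- as.vector(outer(ri, (ci - 1L) * d[1L], `+`))[as.vector(sub)]
    dev <- abs(sweep(flat[pix, , drop = FALSE], 2, mu))
    out_frac <- colMeans(sweep(dev, 2, k_sd * sdv) > 0)
    kept[t] <- !any(out_frac > frac)
  }
  table$kept <- kept
  table
}

#' Spectral pretreatments: SNV and Savitzky-Golay
#'
#' Standard normal variate (SNV) centres each spectrum to mean 0 and scales
#' it to unit sample standard deviation. Savitzky-Golay smoothing fits a
#' local polynomial of order `poly_order` in a window of `window` bands;
#' polynomials up to that order are reproduced exactly.
#'
#' @param spectrum Numeric intensity vector.
#' @param method `"SNV"`, `"SavitzkyGolay"` or `"SNV+SavitzkyGolay"` (SNV
#'   applied after smoothing).
#' @param window Odd window width in bands (smoothing only).
#' @param poly_order Polynomial order, `< window`.
#' @export
pretreat_spectrum <- function(spectrum,
                              method = c("SNV", "SavitzkyGolay",
                                         "SNV+SavitzkyGolay"),
                              window = 11L, poly_order = 2L) {
  method <- match.arg(method)
  x <- as.numeric(spectrum)
  if (grepl("SavitzkyGolay", method)) {
    if (window %% 2L == 0L) stop_f("`window` must be odd")
    if (window <= poly_order) stop_f("`window` must exceed `poly_order`")
    x <- as.numeric(signal::sgolayfilt(x, p = poly_order, n = window))
  }
  if (grepl("SNV", method)) {
    s <- stats::sd(x)
    if (s == 0) stop_f("SNV undefined for a constant spectrum")
    x <- (x - mean(x)) / s
  }
  x
}

#' Run the fixed preprocessing chain on a raw cube
#'
#' Applies, in order: white/dark calibration (reflectance modes), exposure
#' scaling, mask construction, 10x10 voxelization, and outlier-voxel
#' flagging; optionally a spectral pretreatment. Every parameter actually
#' applied is recorded in the `provenance` attribute of the result.
#'
#' @param cube Raw [hypercube()].
#' @param block,mask_threshold,outlier_frac,sd_mult,reference_exposure_ms
#'   Stage parameters.
#' @param pretreat `NULL` or a [pretreat_spectrum()] method name.
#' @param keep_excluded Keep `kept = FALSE` rows in the output (default
#'   drops them).
#' @inheritParams voxelize
#' @return A [new_voxel_table()] with a `provenance` attribute.
#' @export
preprocess_cube <- function(cube, block = 10L, mask_threshold = 0.2,
                            outlier_frac = 0.10, sd_mult = 2.0,
                            reference_exposure_ms = cube$exposure_ms,
                            pretreat = NULL, keep_excluded = FALSE,
                            fillet_id = 1L, species = "unknown",
                            day = NA_real_) {
  if (!is.null(cube$white_frame) && !is.null(cube$dark_frame))
    cube <- calibrate_cube(cube)
  cube <- scale_for_exposure(cube, reference_exposure_ms)
  mask <- build_mask(cube, threshold = mask_threshold)
  tab <- voxelize(cube, mask, block, fillet_id, species, day)
  tab <- flag_outlier_voxels(cube, tab, mask, outlier_frac, sd_mult)
  if (!keep_excluded) tab <- subset_voxel_table(tab, tab$kept)
  if (!is.null(pretreat)) {
    sm <- t(apply(spectra_matrix(tab), 1, pretreat_spectrum, method = pretreat))
    tab[, band_columns(tab)] <- sm
  }
  attr(tab, "provenance") <- list(
    block = block, mask_threshold = mask_threshold,
    outlier_frac = outlier_frac, sd_mult = sd_mult,
    reference_exposure_ms = reference_exposure_ms,
    pretreat = pretreat %||% "none")
  tab
}
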