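#' Voxel spectra tables
#'
#' A `voxel_table` is the unit record for all machine learning in the
#' pipeline: one row per spatially averaged 10x10 pixel block ("voxel"),
#' with metadata columns (`voxel_id`, `fillet_id`, `species`, `day`,
#' `block_row`, `block_col`, `kept`) followed by one intensity column per
#' band, named by its wavelength in nm. The wavelength grid and mode are
#' carried as attributes; `spectra_matrix()` extracts the numeric band block
#' and `table_wavelengths()` the grid (both recover them from the column
#' names, so they survive ordinary data-frame subsetting).
#'
#' @param meta Data frame of metadata columns.
#' @param spectra Numeric matrix, rows matching `meta`, one column per band.
#' @param wavelengths Band centres in nm.
#' @param mode Spectral mode tag.
#' @return A data frame of class `voxel_table`.
#' @export
new_voxel_table <- function(meta, spectra, wavelengths, mode) {
  stopifnot(nrow(meta) == nrow(spectra),
            ncol(spectra) == length(wavelengths))
  colnames(spectra) <- format_wl(wavelengths)
  out <- cbind(meta, as.data.frame(spectra, check.names = FALSE))
  attr(out, "wavelengths") <- as.numeric(wavelengths)
  attr(out, "mode") <- match_mode(mode)
  class(out) <- c("voxel_table", "data.frame")
  out
}

format_wl <- function(wl) formatC(wl, format = "f", digits = 2)

band_columns <- function(table) {
  grep("^[0-9]+(\\.[0-9]+)?$", names(table), value = TRUE)
}

#' @rdname new_voxel_table
#' @param table A `voxel_table` (or any data frame with wavelength-named
#'   band columns).
#' @export
spectra_matrix <- function(table) {
  bc <- band_columns(table)
  if (!length(bc)) stop_f("no band columns found in table")
  as.matrix(table[, bc, drop = FALSE])
}

#' @rdname new_voxel_table
#' @export
table_wavelengths <- function(table) {
  wl <- attr(table, "wavelengths")
  if (!is.null(wl)) return(wl)
  as.numeric(band_columns(table))
}

#' Read and write voxel tables as CSV
#'
#' The CSV layout is the metadata columns followed by one column per band
#' named by wavelength; it round-trips through `write_voxel_table()` /
#' `read_voxel_table()`.
#'
#' @param table A `voxel_table`.
#' @param path File path.
#' @param mode Mode tag to attach on read (guessed from the wavelength range
#'   when omitted).
#' @export
write_voxel_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_table
#' @export
read_voxel_table <- function(path, mode = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  bc <- band_columns(df)
  if (!length(bc)) stop_f("no wavelength-named band columns in %s", path)
  wl <- as.numeric(bc)
  if (is.null(mode)) {
    mode <- if (max(wl) > 1100) "SWIR" else if (min(wl) < 430) "VISNIR" else "FL"
  }
  meta <- df[, setdiff(names(df), bc), drop = FALSE]
  new_voxel_table(meta, as.matrix(df[, bc, drop = FALSE]), wl, mode)
}

# rebuild a voxel_table after filtering rows, keeping attributes
subset_voxel_table <- function(table, idx) {
  out <- table[idx, , drop = FALSE]
  attr(out, "wavelengths") <- table_wavelengths(table)
  attr(out, "mode") <- attr(table, "mode")
  class(out) <- c("voxel_table", "data.frame")
  rownames(out) <- NULL
  out
}
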