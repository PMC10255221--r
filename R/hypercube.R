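#' Spectral modes and their instrument geometry
#'
#' The pipeline handles three line-scan imaging modes: fluorescence emission
#' under 365 nm excitation (`"FL"`, 60 bands over 438--718 nm), visible/
#' near-infrared reflectance (`"VISNIR"`, 125 bands over 419--1007 nm) and
#' short-wave-infrared reflectance (`"SWIR"`, 287 bands over 842--2532 nm).
#' `mode_wavelengths()` returns the canonical band-centre grid of a mode and
#' `mode_geometry()` its default spatial image size (rows x cols).
#'
#' @param mode One of `"FL"`, `"VISNIR"`, `"SWIR"`.
#' @return `mode_wavelengths()`: numeric vector of band centres in nm;
#'   `mode_geometry()`: integer vector `c(rows, cols)`.
#' @export
mode_wavelengths <- function(mode) {
  mode <- match_mode(mode)
  switch(mode,
    FL     = seq(438, 718, length.out = 60L),
    VISNIR = seq(419, 1007, length.out = 125L),
    SWIR   = seq(842, 2532, length.out = 287L)
  )
}

#' @rdname mode_wavelengths
#' @export
mode_geometry <- function(mode) {
  mode <- match_mode(mode)
  switch(mode,
    FL     = c(500L, 280L),
    VISNIR = c(500L, 280L),
    SWIR   = c(384L, 350L)
  )
}

match_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L)
    stop_f("`mode` must be a single string")
  m <- toupper(mode)
  if (!m %in% c("FL", "VISNIR", "SWIR"))
    stop_f("unknown spectral mode '%s' (expected FL, VISNIR or SWIR)", mode)
  m
}

#' Construct a hyperspectral cube
#'
#' A hypercube is the raw unit of line-scan hyperspectral imaging: a 3-D
#' intensity array (rows x cols x bands) together with its band wavelengths,
#' mode tag, exposure time, saturation ceiling and, for reflectance modes,
#' per-line-pixel white/dark reference frames (rows x bands matrices, shared
#' across scan lines as the instruments record them).
#'
#' @param data Numeric 3-D array, rows x cols x bands.
#' @param wavelengths Strictly increasing numeric vector, one value per band,
#'   in nm.
#' @param mode Spectral mode tag, see [mode_wavelengths()].
#' @param exposure_ms Exposure time in milliseconds (> 0).
#' @param white_frame,dark_frame Optional reference frames: either rows x
#'   bands matrices (per line pixel, per band) or arrays matching `data`.
#' @param saturation_ceiling Intensity value at which the detector clips.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, mode, exposure_ms = 100,
                      white_frame = NULL, dark_frame = NULL,
                      saturation_ceiling = Inf) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_f("`data` must be a 3-D array (rows x cols x bands)")
  mode <- match_mode(mode)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop_f("length(wavelengths) [%d] does not match band count [%d]",
           length(wavelengths), dim(data)[3L])
  if (any(diff(wavelengths) <= 0))
    stop_f("`wavelengths` must be strictly increasing")
  assert_scalar_number(exposure_ms, "exposure_ms")
  if (exposure_ms <= 0) stop_f("`exposure_ms` must be positive")
  if (is.finite(saturation_ceiling) && any(data > saturation_ceiling))
    stop_f("stored intensities exceed the saturation ceiling")
  for (nm in c("white_frame", "dark_frame")) {
    f <- get(nm)
    if (!is.null(f)) {
      ok <- (is.matrix(f) && all(dim(f) == dim(data)[c(1L, 3L)])) ||
        (is.array(f) && length(dim(f)) == 3L && all(dim(f) == dim(data)))
      if (!ok) stop_f("`%s` must be a rows x bands matrix or match dim(data)", nm)
    }
  }
  structure(
    list(data = data, wavelengths = wavelengths, mode = mode,
         exposure_ms = exposure_ms, white_frame = white_frame,
         dark_frame = dark_frame, saturation_ceiling = saturation_ceiling),
    class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %s  %d x %d x %d  (%.1f-%.1f nm)  exposure %g ms\n",
              x$mode, d[1L], d[2L], d[3L],
              min(x$wavelengths), max(x$wavelengths), x$exposure_ms))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# expand a rows x bands reference frame to the full cube shape on demand
frame_as_cube <- function(frame, dims) {
  if (is.null(frame)) return(NULL)
  if (is.matrix(frame)) {
    # rows x bands -> rows x cols x bands
    aperm(array(rep(frame, dims[2L]),
                dim = c(dims[1L], dims[3L], dims[2L])), c(1L, 3L, 2L))
  } else frame
}
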