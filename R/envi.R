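#' Read and write hypercubes in ENVI format
#'
#' The community interchange format for line-scan hyperspectral imaging: a
#' flat binary file plus a text header (`.hdr`) giving `samples` (columns),
#' `lines` (rows), `bands`, `data type` (4 = float32, 5 = float64),
#' `interleave` (BIL, BSQ or BIP), `byte order` and the wavelength list.
#' `write_envi_cube()` also records the mode tag and exposure time so a
#' round trip preserves the full [hypercube()]; float64 round trips are
#' bit-identical.
#'
#' @param cube A [hypercube()].
#' @param path Path of the binary file; the header is written at
#'   `<path>.hdr`.
#' @param interleave `"bil"`, `"bsq"` or `"bip"`.
#' @param data_type 4 (float32) or 5 (float64).
#' @return `read_envi_cube()`: a [hypercube()]; `write_envi_cube()`: `path`,
#'   invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                            data_type = 5L) {
  if (!inherits(cube, "hypercube")) stop_f("`cube` must be a hypercube")
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop_f("data type must be 4 or 5")
  d <- dim(cube$data) # rows(lines) x cols(samples) x bands
  hdr <- c(
    "ENVI",
    "description = {freshspec hypercube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("mode = %s", cube$mode),
    sprintf("exposure ms = %g", cube$exposure_ms),
    sprintf("wavelength units = nm"),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, digits = 15),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # reorder: BIL = [sample, band, line], BSQ = [sample, line, band],
  # BIP = [band, sample, line]; fastest-varying first
  arr <- switch(interleave,
    bil = aperm(cube$data, c(2L, 3L, 1L)),
    bsq = aperm(cube$data, c(2L, 1L, 3L)),
    bip = aperm(cube$data, c(3L, 2L, 1L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(arr), con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  invisible(path)
}

#' @rdname write_envi_cube
#' @export
read_envi_cube <- function(path) {
  hdr_path <- if (file.exists(paste0(path, ".hdr"))) paste0(path, ".hdr")
  else sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path)) stop_f("missing ENVI header for %s", path)
  if (!file.exists(path)) stop_f("missing ENVI binary %s", path)
  hdr <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(hdr[[k]])) stop_f("ENVI header lacks '%s'", k)
  if (is.null(hdr[["wavelength"]]))
    stop_f("ENVI header lacks a wavelength list")
  nr <- as.integer(hdr[["lines"]]); nc <- as.integer(hdr[["samples"]])
  nb <- as.integer(hdr[["bands"]])
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1L]])
  if (length(wl) != nb)
    stop_f("header declares %d bands but lists %d wavelengths", nb, length(wl))
  dt <- as.integer(hdr[["data type"]])
  if (!dt %in% c(4L, 5L)) stop_f("unsupported ENVI data type %d", dt)
  size <- if (dt == 4L) 4L else 8L
  n <- nr * nc * nb
  if (file.size(path) != n * size)
    stop_f("binary size (%d bytes) does not match header shape", file.size(path))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = size, endian = "little")
  interleave <- tolower(hdr[["interleave"]])
  data <- switch(interleave,
    bil = aperm(array(v, c(nc, nb, nr)), c(3L, 1L, 2L)),
    bsq = aperm(array(v, c(nc, nr, nb)), c(2L, 1L, 3L)),
    bip = aperm(array(v, c(nb, nc, nr)), c(3L, 2L, 1L)),
    stop_f("unsupported interleave '%s'", interleave))
  hypercube(data, wl, mode = hdr[["mode"]] %||% "FL",
            exposure_ms = as.numeric(hdr[["exposure ms"]] %||% 100))
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines[-1L], collapse = "\n") # drop the ENVI magic line
  # join brace-delimited multi-line values, then strip the braces
  m <- gregexpr("\\{[^}]*\\}", txt)
  regmatches(txt, m) <- lapply(regmatches(txt, m),
                               function(s) gsub("\n", " ", s))
  txt <- gsub("[{}]", "", txt)
  out <- list()
  for (ln in strsplit(txt, "\n")[[1L]]) {
    if (!grepl("=", ln, fixed = TRUE)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(tolower(kv[1L]))
    out[[key]] <- trimws(paste(kv[-1L], collapse = "="))
  }
  out
}
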