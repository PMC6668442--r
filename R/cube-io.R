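# Reading and writing hyperspectral cubes and stage outputs.
#
# Two on-disk dialects are supported for cubes: an ENVI header/binary pair
# (band-sequential float32, the lingua franca of imaging spectrometers) and a
# packaged-array archive (an RDS file holding `cube`, `wavenumbers_cm1` and
# `pixel_size_um`). Physical coordinates follow the convention
# coordinate = (0-based pixel index + 0.5) * pixel size.

#' Write a cube as an ENVI header/binary pair
#'
#' @param cube a [spectral_cube()]
#' @param path path of the binary file; the header is written alongside as
#'   `<path>.hdr`
#' @return `path`, invisibly
#' @export
write_cube_envi <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$absorbance)
  hdr <- c(
    "ENVI",
    "description = {chromamech absorbance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = cm-1",
    sprintf("pixel size um = %.10g", cube$pixel_size_um),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavenumbers, trim = TRUE, digits = 12),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) { # BSQ: samples (cols) fastest, then lines, then bands
    writeBin(as.numeric(t(cube$absorbance[, , b])), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

read_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*([-0-9.eE+]+)"), txt))[[1]]
    if (length(m) < 2L) return(NULL)
    as.numeric(m[2])
  }
  wl <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wl) < 2L) {
    stopf("ENVI header %s has no wavelength list", hdr_path,
          class = "chromamech_format_error")
  }
  list(
    samples = get_num("samples"), lines = get_num("lines"),
    bands = get_num("\nbands"), data_type = get_num("data type"),
    interleave = regmatches(txt, regexec("interleave\\s*=\\s*(\\w+)", txt))[[1]][2],
    pixel_size_um = get_num("pixel size um"),
    wavelengths = as.numeric(strsplit(wl[2], ",")[[1]])
  )
}

read_cube_envi <- function(path, pixel_size_um = NULL) {
  hdr_path <- if (file.exists(paste0(path, ".hdr"))) paste0(path, ".hdr")
              else sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path)) {
    stopf("no ENVI header found for %s", path, class = "chromamech_format_error")
  }
  h <- read_envi_header(hdr_path)
  if (is.null(h$samples) || is.null(h$lines) || is.null(h$bands)) {
    stopf("ENVI header %s is missing dimensions", hdr_path,
          class = "chromamech_format_error")
  }
  if (!identical(h$data_type, 4) || !identical(tolower(h$interleave), "bsq")) {
    stopf("only float32 BSQ ENVI cubes are supported (data type %s, interleave %s)",
          h$data_type, h$interleave, class = "chromamech_format_error")
  }
  if (length(h$wavelengths) != h$bands) {
    stopf("ENVI header lists %d wavelengths for %d bands",
          length(h$wavelengths), h$bands, class = "chromamech_format_error")
  }
  n_expected <- h$samples * h$lines * h$bands
  actual_bytes <- file.info(path)$size
  if (actual_bytes != 4 * n_expected) {
    stopf("ENVI binary %s has %d bytes; expected %d (%d x %d x %d float32)",
          path, actual_bytes, 4 * n_expected, h$lines, h$samples, h$bands,
          class = "chromamech_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = n_expected, size = 4,
                  endian = "little")
  cube <- array(0, dim = c(h$lines, h$samples, h$bands))
  per_band <- h$lines * h$samples
  for (b in seq_len(h$bands)) {
    cube[, , b] <- matrix(vals[((b - 1) * per_band + 1):(b * per_band)],
                          h$lines, h$samples, byrow = TRUE)
  }
  spectral_cube(cube, h$wavelengths,
                pixel_size_um %||% h$pixel_size_um %||% 1)
}

#' Write a cube as a packaged-array archive
#'
#' The archive is an RDS file holding `cube` (rows x cols x bands),
#' `wavenumbers_cm1` and `pixel_size_um`; unlike the float32 ENVI pair it
#' round-trips at full double precision.
#'
#' @param cube a [spectral_cube()]
#' @param path output path (conventionally `.rds`)
#' @return `path`, invisibly
#' @export
write_cube_archive <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  saveRDS(list(cube = cube$absorbance, wavenumbers_cm1 = cube$wavenumbers,
               pixel_size_um = cube$pixel_size_um), path)
  invisible(path)
}

#' Read a hyperspectral cube
#'
#' Accepts either dialect written by [write_cube_envi()] /
#' [write_cube_archive()]. The returned wavenumber axis is always ascending;
#' cubes stored with a descending axis have their bands reversed consistently.
#'
#' @param path cube path (ENVI binary with sibling `.hdr`, or `.rds` archive)
#' @param format `"auto"` (by extension/sibling), `"envi"` or `"archive"`
#' @param pixel_size_um optional override for the stored pixel size
#' @return a [spectral_cube()]
#' @export
read_cube <- function(path, format = c("auto", "envi", "archive"),
                      pixel_size_um = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stopf("cube file %s does not exist", path, class = "chromamech_format_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "archive" else "envi"
  }
  if (format == "archive") {
    x <- readRDS(path)
    if (!all(c("cube", "wavenumbers_cm1") %in% names(x))) {
      stopf("archive %s lacks `cube`/`wavenumbers_cm1`", path,
            class = "chromamech_format_error")
    }
    spectral_cube(x$cube, x$wavenumbers_cm1,
                  pixel_size_um %||% x$pixel_size_um %||% 1)
  } else {
    read_cube_envi(path, pixel_size_um)
  }
}

#' Write a label image as a 16-bit single-page TIFF
#'
#' @param labels integer label matrix (0 = background)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a label image written by [write_labels_tiff()]
#' @param path TIFF path
#' @return integer label matrix
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write per-cell spectra as CSV
#'
#' First column `cell_id` (and `group` when present), then one column per
#' wavenumber; the header row carries the wavenumbers in cm^-1.
#'
#' @param spectra a [cell_spectra()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "cell_spectra"))
  utils::write.csv(as.data.frame(spectra), path, row.names = FALSE)
  invisible(path)
}

#' Read per-cell spectra written by [write_spectra_csv()]
#' @param path CSV path
#' @return a [cell_spectra()]
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  has_group <- "group" %in% names(df)
  meta_cols <- c("cell_id", if (has_group) "group")
  wn <- as.numeric(setdiff(names(df), meta_cols))
  cell_spectra(
    wavenumbers = wn,
    absorbance = as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]),
    cell_id = df$cell_id,
    group = if (has_group) df$group else NULL
  )
}

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' @param frames list of numeric matrices with values in `[0, 1]`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_video_tiff <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a list of frames
#' @param path TIFF path
#' @return list of numeric matrices in `[0, 1]`
#' @export
read_video_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames
}
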