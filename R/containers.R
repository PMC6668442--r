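# Core data containers for the FTIR arm.

#' Hyperspectral absorbance cube
#'
#' A calibrated three-dimensional dataset: two spatial axes and one spectral
#' axis. The wavenumber axis is always stored ascending; readers reorder
#' descending input (see [read_cube()]).
#'
#' @param absorbance numeric array, `rows x cols x bands`; all values finite
#' @param wavenumbers strictly monotonic wavenumber axis, cm^-1, one entry
#'   per band
#' @param pixel_size_um pixel edge length, um
#' @return a `spectral_cube` object
#' @export
spectral_cube <- function(absorbance, wavenumbers, pixel_size_um) {
  if (!is.array(absorbance) || length(dim(absorbance)) != 3L) {
    stopf("absorbance must be a 3-D array (rows x cols x bands)")
  }
  if (dim(absorbance)[3] != length(wavenumbers)) {
    stopf("bands dimension (%d) does not match wavenumber axis length (%d)",
          dim(absorbance)[3], length(wavenumbers),
          class = "chromamech_format_error")
  }
  d <- diff(wavenumbers)
  if (length(wavenumbers) < 2L || !(all(d > 0) || all(d < 0))) {
    stopf("wavenumber axis must be strictly monotonic",
          class = "chromamech_data_error")
  }
  if (all(d < 0)) { # store ascending
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, , rev(seq_len(dim(absorbance)[3])), drop = FALSE]
  }
  if (!all(is.finite(absorbance))) {
    stopf("absorbance contains non-finite values", class = "chromamech_data_error")
  }
  stopifnot(pixel_size_um > 0)
  structure(
    list(absorbance = absorbance, wavenumbers = wavenumbers,
         pixel_size_um = pixel_size_um),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(sprintf(
    "<spectral_cube> %d x %d pixels (%.2f um/px), %d bands [%g, %g] cm^-1\n",
    d[1], d[2], x$pixel_size_um, d[3], min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$absorbance)

#' Per-cell spectra
#'
#' Column-bound average (or simulated) spectra for a set of cells, together
#' with per-cell metadata. The preprocessing applied so far is recorded in
#' the `provenance` attribute-like field, in order of application.
#'
#' @param wavenumbers wavenumber axis, cm^-1
#' @param absorbance matrix, one row per cell, one column per wavenumber
#' @param cell_id integer cell identifiers
#' @param pixel_count pixels averaged per cell (NA for simulated spectra)
#' @param centroid optional matrix of (row, col) pixel centroids
#' @param group optional per-cell group labels
#' @param provenance ordered character vector of processing steps applied
#' @param qc_flag per-cell quality flag; `""` means usable
#' @return a `cell_spectra` object
#' @export
cell_spectra <- function(wavenumbers, absorbance, cell_id,
                         pixel_count = rep(NA_integer_, length(cell_id)),
                         centroid = NULL, group = NULL,
                         provenance = character(),
                         qc_flag = rep("", length(cell_id))) {
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavenumbers)) {
    stopf("absorbance has %d columns but wavenumber axis has %d entries",
          ncol(absorbance), length(wavenumbers))
  }
  if (nrow(absorbance) != length(cell_id)) {
    stopf("absorbance has %d rows but %d cell ids were given",
          nrow(absorbance), length(cell_id))
  }
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         cell_id = as.integer(cell_id), pixel_count = pixel_count,
         centroid = centroid, group = group, provenance = provenance,
         qc_flag = qc_flag),
    class = "cell_spectra"
  )
}

#' @export
print.cell_spectra <- function(x, ...) {
  cat(sprintf("<cell_spectra> %d cells, %d wavenumbers [%g, %g] cm^-1\n",
              nrow(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$provenance)) {
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Number of cells in a `cell_spectra` object
#' @param x a [cell_spectra()] object
#' @return integer cell count
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "cell_spectra"))
  nrow(x$absorbance)
}

#' @export
as.data.frame.cell_spectra <- function(x, ...) {
  df <- data.frame(cell_id = x$cell_id, x$absorbance, check.names = FALSE)
  names(df) <- c("cell_id", format(x$wavenumbers, trim = TRUE))
  if (!is.null(x$group)) df <- cbind(df[1], group = x$group, df[-1])
  df
}
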