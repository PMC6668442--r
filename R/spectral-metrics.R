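# Per-cell spectral preprocessing and integrated peak-ratio metrics.
#
# The processing chain follows standard biological FTIR practice: restrict to
# the fingerprint region (1800-1000 cm^-1), subtract an offset baseline
# anchored at 1800 cm^-1 where cells are spectrally silent, normalize to the
# Amide I peak maximum (1710-1650 cm^-1) to cancel thickness/density, then
# integrate peaks above a local straight baseline drawn through the troughs
# on each side of the peak. The DNA-to-protein ratio divides the symmetric
# phosphate stretch integral (1070-1035 cm^-1, DNA backbone) by the Amide II
# integral (1580-1490 cm^-1, protein; preferred over Amide I which can carry
# a water-bending contribution).

#' Default analysis band registry
#'
#' @return named list of `c(lo, hi)` wavenumber windows, cm^-1:
#'   `amide1_image` (chemical-image window), `amide1_norm` (normalization
#'   window), `amide2` (protein denominator), `nu_s_po2` (DNA numerator)
#' @export
default_bands <- function() {
  list(
    amide1_image = c(1625, 1675),
    amide1_norm  = c(1650, 1710),
    amide2       = c(1490, 1580),
    nu_s_po2     = c(1035, 1070)
  )
}

#' Crop spectra to the fingerprint region
#'
#' @param x a [cell_spectra()]
#' @param lo,hi region bounds, cm^-1
#' @return the cropped [cell_spectra()]; provenance gains `"crop"`
#' @export
crop_fingerprint <- function(x, lo = 1000, hi = 1800) {
  stopifnot(inherits(x, "cell_spectra"), lo < hi)
  wn <- x$wavenumbers
  if (min(wn) > lo || max(wn) < hi) {
    stopf("spectra cover [%g, %g] cm^-1 but [%g, %g] was requested",
          min(wn), max(wn), lo, hi, class = "chromamech_coverage_error")
  }
  idx <- window_idx(wn, lo, hi, "fingerprint region")
  x$wavenumbers <- wn[idx]
  x$absorbance <- x$absorbance[, idx, drop = FALSE]
  x$provenance <- c(x$provenance, "crop")
  x
}

#' Subtract an offset baseline anchored at one wavenumber
#'
#' The absorbance at the anchor (linearly interpolated when the anchor falls
#' between grid points) is subtracted from every sample of each spectrum, so
#' the anchor value becomes exactly zero.
#'
#' @param x a [cell_spectra()]
#' @param anchor anchor wavenumber, cm^-1
#' @return the corrected [cell_spectra()]; provenance gains `"baseline"`
#' @export
baseline_offset <- function(x, anchor = 1800) {
  stopifnot(inherits(x, "cell_spectra"))
  wn <- x$wavenumbers
  if (anchor < min(wn) || anchor > max(wn)) {
    stopf("baseline anchor %g cm^-1 outside axis [%g, %g]",
          anchor, min(wn), max(wn), class = "chromamech_range_error")
  }
  if (nrow(x$absorbance) > 0L) {
    at_anchor <- apply(x$absorbance, 1L, function(y) interp_at(wn, y, anchor))
    x$absorbance <- x$absorbance - at_anchor
  }
  x$provenance <- c(x$provenance, "baseline")
  x
}

#' Normalize spectra to the Amide I peak maximum
#'
#' Each spectrum is divided by its maximum over the normalization window, so
#' the post-normalization window maximum is exactly 1. Cells whose window
#' maximum is not positive cannot be normalized: they are either flagged
#' (`qc_flag = "nonpositive_amide1"`, row left untouched, excluded from
#' downstream ratios) or raised as an error.
#'
#' @param x a [cell_spectra()]
#' @param window `c(lo, hi)` normalization window, cm^-1
#' @param on_invalid `"error"` (default for direct calls) or `"flag"`
#' @return the normalized [cell_spectra()]; provenance gains `"normalize"`
#' @export
normalize_amide1 <- function(x, window = c(1650, 1710),
                             on_invalid = c("error", "flag")) {
  stopifnot(inherits(x, "cell_spectra"), length(window) == 2L,
            window[1] < window[2])
  on_invalid <- match.arg(on_invalid)
  wn <- x$wavenumbers
  if (window[1] < min(wn) || window[2] > max(wn)) {
    stopf("normalization window [%g, %g] outside axis [%g, %g]",
          window[1], window[2], min(wn), max(wn),
          class = "chromamech_range_error")
  }
  idx <- window_idx(wn, window[1], window[2], "normalization window")
  if (nrow(x$absorbance) > 0L) {
    peak <- apply(x$absorbance[, idx, drop = FALSE], 1L, max)
    bad <- peak <= 0
    if (any(bad) && on_invalid == "error") {
      stopf("Amide I window maximum is not positive for cell(s) %s",
            paste(x$cell_id[bad], collapse = ", "),
            class = "chromamech_nonpositive_peak")
    }
    scale <- ifelse(bad, 1, peak)
    x$absorbance <- x$absorbance / scale
    x$qc_flag[bad] <- "nonpositive_amide1"
  }
  x$provenance <- c(x$provenance, "normalize")
  x
}

#' Full preprocessing chain: crop, offset baseline, Amide I normalization
#'
#' @param x a [cell_spectra()]
#' @param fingerprint `c(lo, hi)` crop bounds, cm^-1
#' @param anchor offset-baseline anchor, cm^-1
#' @param norm_window Amide I normalization window, cm^-1
#' @return the processed [cell_spectra()] with provenance
#'   `crop -> baseline -> normalize`; non-normalizable cells are flagged
#' @export
preprocess_spectra <- function(x, fingerprint = c(1000, 1800), anchor = 1800,
                               norm_window = c(1650, 1710)) {
  x <- crop_fingerprint(x, fingerprint[1], fingerprint[2])
  x <- baseline_offset(x, anchor)
  normalize_amide1(x, norm_window, on_invalid = "flag")
}

#' Integrate a peak above a local trough-to-trough baseline
#'
#' The left trough is the position of minimum absorbance in
#' `[lo - margin, lo]`, the right trough the minimum in `[hi, hi + margin]`.
#' A straight baseline is drawn through the two trough points and the
#' trapezoidal integral of the spectrum above that baseline is taken over the
#' trough-to-trough span, with below-baseline contributions clipped to zero
#' (an integrated peak intensity is non-negative by construction).
#'
#' @param wavenumbers ascending wavenumber axis, cm^-1
#' @param absorbance absorbance vector on that axis
#' @param band `c(lo, hi)` nominal peak window, cm^-1 (delimits the trough
#'   search; integration runs trough to trough)
#' @param margin trough search extent beyond each band edge, cm^-1
#' @return list: `integral` ((normalized absorbance) x cm^-1), `left_trough`
#'   and `right_trough` positions (cm^-1), their absorbance values, and
#'   `at_edge` flags marking troughs found at the search-window edges
#' @export
integrate_peak <- function(wavenumbers, absorbance, band, margin = 30) {
  stopifnot(length(band) == 2L, band[1] < band[2], margin >= 0)
  wn <- wavenumbers
  if (band[1] - margin < min(wn) || band[2] + margin > max(wn)) {
    stopf("band [%g, %g] plus margin %g exceeds axis [%g, %g]",
          band[1], band[2], margin, min(wn), max(wn),
          class = "chromamech_range_error")
  }
  li <- window_idx(wn, band[1] - margin, band[1], "left trough window")
  ri <- window_idx(wn, band[2], band[2] + margin, "right trough window")
  il <- li[which.min(absorbance[li])]
  ir <- ri[which.min(absorbance[ri])]
  wl <- wn[il]; yl <- absorbance[il]
  wr <- wn[ir]; yr <- absorbance[ir]

  span <- il:ir
  baseline <- yl + (yr - yl) * (wn[span] - wl) / (wr - wl)
  integrand <- pmax(absorbance[span] - baseline, 0)
  list(
    integral = trapezoid(wn[span], integrand),
    left_trough = wl, right_trough = wr,
    left_value = yl, right_value = yr,
    at_edge = c(left = il == li[1], right = ir == ri[length(ri)])
  )
}

#' DNA-to-protein integrated peak ratio for one spectrum
#'
#' Ratio of the trough-baselined integrated symmetric phosphate stretch
#' (DNA) to the trough-baselined integrated Amide II peak (protein). The
#' spectrum is expected to be preprocessed (crop, offset baseline, Amide I
#' normalization).
#'
#' @param wavenumbers ascending wavenumber axis, cm^-1
#' @param absorbance preprocessed absorbance vector
#' @param num_band numerator window, cm^-1 (symmetric phosphate stretch)
#' @param den_band denominator window, cm^-1 (Amide II)
#' @param margin trough search margin, cm^-1
#' @param cell_id optional identifier carried into the result
#' @return a `peak_ratio` object: numerator/denominator integrals, their
#'   trough positions, and `ratio = numerator/denominator`
#' @export
dna_protein_ratio <- function(wavenumbers, absorbance,
                              num_band = c(1035, 1070),
                              den_band = c(1490, 1580),
                              margin = 30, cell_id = NA_integer_) {
  num <- integrate_peak(wavenumbers, absorbance, num_band, margin)
  den <- integrate_peak(wavenumbers, absorbance, den_band, margin)
  if (den$integral <= 0) {
    stopf("Amide II integral is not positive (cell %s); cell must be excluded",
          cell_id, class = "chromamech_invalid_cell")
  }
  structure(
    list(cell_id = cell_id,
         num_band = num_band, num_integral = num$integral,
         den_band = den_band, den_integral = den$integral,
         ratio = num$integral / den$integral,
         troughs = list(num = c(num$left_trough, num$right_trough),
                        den = c(den$left_trough, den$right_trough))),
    class = "peak_ratio"
  )
}

#' @export
print.peak_ratio <- function(x, ...) {
  cat(sprintf("<peak_ratio> cell %s: %.4f (num %.4f / den %.4f)\n",
              x$cell_id, x$ratio, x$num_integral, x$den_integral))
  invisible(x)
}

#' DNA-to-protein ratios for a set of cells
#'
#' Applies [dna_protein_ratio()] to every cell of a preprocessed
#' [cell_spectra()]. Cells already flagged by preprocessing, or whose
#' denominator integral is not positive, get `ratio = NA` and a `qc_flag`
#' instead of being silently dropped.
#'
#' @param x a preprocessed [cell_spectra()]
#' @param num_band,den_band,margin see [dna_protein_ratio()]
#' @return data frame with one row per cell: `cell_id`, `group` (when
#'   known), integrals, `ratio`, trough positions, and `qc_flag`
#' @export
compute_ratios <- function(x, num_band = c(1035, 1070),
                           den_band = c(1490, 1580), margin = 30) {
  stopifnot(inherits(x, "cell_spectra"))
  n <- nrow(x$absorbance)
  out <- data.frame(
    cell_id = x$cell_id,
    group = if (!is.null(x$group)) x$group else rep(NA_character_, n),
    num_integral = rep(NA_real_, n), den_integral = rep(NA_real_, n),
    ratio = rep(NA_real_, n),
    left_trough_num = rep(NA_real_, n), right_trough_num = rep(NA_real_, n),
    left_trough_den = rep(NA_real_, n), right_trough_den = rep(NA_real_, n),
    qc_flag = x$qc_flag,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    if (nzchar(out$qc_flag[i])) next
    res <- tryCatch(
      dna_protein_ratio(x$wavenumbers, x$absorbance[i, ], num_band, den_band,
                        margin, cell_id = x$cell_id[i]),
      chromamech_invalid_cell = function(e) NULL
    )
    if (is.null(res)) {
      out$qc_flag[i] <- "nonpositive_denominator"
      next
    }
    out$num_integral[i] <- res$num_integral
    out$den_integral[i] <- res$den_integral
    out$ratio[i] <- res$ratio
    out$left_trough_num[i] <- res$troughs$num[1]
    out$right_trough_num[i] <- res$troughs$num[2]
    out$left_trough_den[i] <- res$troughs$den[1]
    out$right_trough_den[i] <- res$troughs$den[2]
  }
  out
}
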