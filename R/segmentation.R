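# Single-cell segmentation of FTIR chemical images.
#
# Cells are located on the Amide I chemical image (protein signal), separated
# by global Otsu thresholding, and touching cells are split by marker-based
# watershed on the Euclidean distance transform (EBImage primitives).

#' Reduce a cube to a 2-D chemical image over a band
#'
#' @param cube a [spectral_cube()]
#' @param band `c(lo, hi)` wavenumber window, cm^-1; the default is the
#'   Amide I imaging window
#' @param reduction `"peak-maximum"` (per-pixel maximum over the in-band
#'   samples; the default, matching intensity-based cell detection) or
#'   `"integral"` (per-pixel trapezoidal integral over the window)
#' @return a `chemical_image` object: matrix `values` plus the band and
#'   reduction used
#' @export
chemical_image <- function(cube, band = c(1625, 1675),
                           reduction = c("peak-maximum", "integral")) {
  stopifnot(inherits(cube, "spectral_cube"), length(band) == 2L, band[1] < band[2])
  reduction <- match.arg(reduction)
  wn <- cube$wavenumbers
  if (band[1] < min(wn) || band[2] > max(wn)) {
    stopf("band [%g, %g] outside wavenumber axis [%g, %g]",
          band[1], band[2], min(wn), max(wn), class = "chromamech_range_error")
  }
  idx <- window_idx(wn, band[1], band[2], "chemical image band")
  d <- dim(cube$absorbance)
  sub <- cube$absorbance[, , idx, drop = FALSE]
  values <- if (reduction == "peak-maximum") {
    Reduce(pmax, lapply(seq_along(idx), function(k) sub[, , k]))
  } else {
    x <- wn[idx]
    if (length(idx) == 1L) {
      sub[, , 1]
    } else {
      # trapezoid weights: integral = sum_k w_k y_k
      w <- numeric(length(x))
      dx <- diff(x)
      w[1] <- dx[1] / 2
      w[length(x)] <- dx[length(dx)] / 2
      if (length(x) > 2L) w[2:(length(x) - 1L)] <- (dx[-length(dx)] + dx[-1]) / 2
      matrix(matrix(sub, d[1] * d[2], length(idx)) %*% w, d[1], d[2])
    }
  }
  structure(list(values = values, band = band, reduction = reduction,
                 pixel_size_um = cube$pixel_size_um),
            class = "chemical_image")
}

#' @export
print.chemical_image <- function(x, ...) {
  cat(sprintf("<chemical_image> %d x %d, band [%g, %g] cm^-1, %s\n",
              nrow(x$values), ncol(x$values), x$band[1], x$band[2],
              x$reduction))
  invisible(x)
}

# Marker-based watershed on the Euclidean distance transform: markers are
# local maxima of the distance map with a minimum separation (maxima closer
# than `sep_px` are fused into one marker), and the foreground is partitioned
# between markers by seeded region growing along the distance map
# (EBImage::propagate). Ridge pixels belong to exactly one label.
watershed_split <- function(mask, sep_px) {
  dm <- EBImage::distmap(mask)
  brush_size <- 2L * max(1L, as.integer(floor(sep_px / 2))) + 1L
  dil <- EBImage::dilate(dm, EBImage::makeBrush(brush_size, "disc"))
  cand <- (dm >= dil - 1e-9) & mask
  lbl <- EBImage::bwlabel(cand)
  lbl <- matrix(as.integer(lbl), nrow(mask), ncol(mask))
  n <- max(lbl)
  if (n > 1L) {
    # fuse marker blobs whose centroids sit closer than the seed spacing
    cents <- t(vapply(seq_len(n), function(k) {
      idx <- which(lbl == k)
      c(mean((idx - 1L) %% nrow(lbl)), mean((idx - 1L) %/% nrow(lbl)))
    }, numeric(2)))
    parent <- seq_len(n)
    find_root <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sqrt(sum((cents[i, ] - cents[j, ])^2)) < sep_px) {
          ri <- find_root(i); rj <- find_root(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    root <- vapply(seq_len(n), find_root, integer(1))
    remap <- match(root, unique(root))
    lbl[lbl > 0L] <- remap[lbl[lbl > 0L]]
  }
  ws <- EBImage::propagate(dm, seeds = lbl, mask = mask, lambda = 1e-4)
  matrix(as.integer(ws), nrow(mask), ncol(mask))
}

#' Segment a chemical image into single cells
#'
#' Global Otsu threshold on the image, then marker-based watershed on the
#' Euclidean distance transform of the foreground (markers are distance-map
#' maxima with a configurable minimum separation) to split touching cells,
#' then an area filter removing debris and unsplit clumps. Labels are
#' relabelled 1..n.
#'
#' @param img a [chemical_image()], or a plain matrix (then `pixel_size_um`
#'   must be given)
#' @param min_area_um2,max_area_um2 component area bounds, um^2; components
#'   outside the bounds are removed
#' @param seed_spacing_um minimum separation of watershed seed maxima, um;
#'   about one cell diameter
#' @param pixel_size_um pixel edge length when `img` is a plain matrix
#' @return a `segmentation` object: integer matrix `labels`
#'   (0 = background) and a `params` record
#' @export
segment_cells <- function(img, min_area_um2 = 20, max_area_um2 = 500,
                          seed_spacing_um = 8, pixel_size_um = NULL) {
  if (inherits(img, "chemical_image")) {
    pixel_size_um <- pixel_size_um %||% img$pixel_size_um
    values <- img$values
  } else {
    values <- img
  }
  stopifnot(is.matrix(values), !is.null(pixel_size_um))
  if (!all(is.finite(values))) {
    stopf("image contains non-finite values", class = "chromamech_data_error")
  }
  scaled <- rescale01(values) # errors on constant images
  thr <- EBImage::otsu(scaled, range = c(0, 1))
  mask <- scaled > thr

  labels <- matrix(0L, nrow(values), ncol(values))
  if (any(mask)) {
    sep_px <- seed_spacing_um / pixel_size_um
    labels <- watershed_split(mask, sep_px)
  }

  # area filter in physical units, then compact relabelling
  px_area <- pixel_size_um^2
  if (max(labels) > 0L) {
    counts <- tabulate(labels[labels > 0L])
    keep <- which(counts * px_area >= min_area_um2 &
                  counts * px_area <= max_area_um2)
    remap <- integer(length(counts))
    remap[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }

  structure(
    list(labels = labels,
         params = list(threshold_method = "otsu", threshold = thr,
                       min_area_um2 = min_area_um2,
                       max_area_um2 = max_area_um2,
                       seed_spacing_um = seed_spacing_um,
                       pixel_size_um = pixel_size_um)),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d x %d, %d cells (otsu + watershed)\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

#' Number of labelled cells in a segmentation
#' @param seg a [segment_cells()] result
#' @return integer count
#' @export
n_segments <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  max(seg$labels)
}

#' Average spectrum per segmented cell
#'
#' For every label the unweighted arithmetic mean over that label's pixels is
#' taken at each wavenumber; background pixels never contribute. Each pixel
#' belongs to exactly one label (watershed ridge pixels are assigned by the
#' watershed itself), so no pixel is double-counted.
#'
#' @param cube a [spectral_cube()]
#' @param seg a [segment_cells()] result with the cube's spatial shape
#' @return a [cell_spectra()] with one row per label, with pixel counts and
#'   pixel centroids
#' @export
extract_cell_spectra <- function(cube, seg) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(seg, "segmentation"))
  d <- dim(cube$absorbance)
  if (!identical(dim(seg$labels), d[1:2])) {
    stopf("segmentation shape (%d x %d) does not match cube (%d x %d)",
          nrow(seg$labels), ncol(seg$labels), d[1], d[2],
          class = "chromamech_format_error")
  }
  n <- max(seg$labels)
  if (n == 0L) {
    return(cell_spectra(cube$wavenumbers,
                        matrix(0, 0, length(cube$wavenumbers)),
                        integer(0), pixel_count = integer(0)))
  }
  present <- sort(unique(seg$labels[seg$labels > 0L]))
  if (!identical(present, seq_len(n))) {
    stopf("segmentation labels are not contiguous 1..%d", n,
          class = "chromamech_internal_error")
  }
  idx <- which(seg$labels > 0L)
  lab <- seg$labels[idx]
  mat <- matrix(cube$absorbance, d[1] * d[2], d[3])[idx, , drop = FALSE]
  sums <- rowsum(mat, lab)
  counts <- tabulate(lab, nbins = n)
  means <- sums / counts

  rows <- ((idx - 1L) %% d[1]) + 1L
  cols <- ((idx - 1L) %/% d[1]) + 1L
  centroid <- cbind(row = rowsum(rows, lab)[, 1] / counts,
                    col = rowsum(cols, lab)[, 1] / counts)

  cell_spectra(cube$wavenumbers, means, seq_len(n),
               pixel_count = counts, centroid = centroid)
}
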