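# Synthetic FTIR hyperspectral cubes with full ground truth.
#
# Cells are rendered as compact disks whose pixel spectra are sums of Gaussian
# absorption bands; treatment groups differ by their band amplitudes (chiefly
# the DNA phosphate band). Everything downstream of the instrument can be
# exercised against the planted masks and spectra.

#' Describe one vibrational absorption band
#'
#' A band is modelled as a Gaussian absorbance profile parameterised by its
#' centre wavenumber, full width at half maximum and peak amplitude.
#'
#' @param name text label (e.g. `"Amide I"`)
#' @param center centre wavenumber, cm^-1
#' @param width full width at half maximum, cm^-1; must be positive
#' @param amplitude peak absorbance (dimensionless); must be non-negative
#' @return a `band_model` object
#' @export
#' @examples
#' band_model("Amide I", 1655, 55, 1.0)
band_model <- function(name, center, width, amplitude) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(width) || width <= 0) {
    stopf("band '%s': width must be positive (got %g)", name, width)
  }
  if (!is.finite(amplitude) || amplitude < 0) {
    stopf("band '%s': amplitude must be non-negative (got %g)", name, amplitude)
  }
  structure(
    list(name = name, center = center, width = width, amplitude = amplitude),
    class = "band_model"
  )
}

#' Default band set for simulated B-cell spectra
#'
#' Amide I and II (protein backbone), the CH2/CH3 bending mode, and the
#' antisymmetric and symmetric phosphate stretches of the DNA backbone.
#' Amplitudes are uncalibrated free parameters (absolute absorbance levels of
#' real cells are instrument- and thickness-dependent); the DNA band amplitude
#' can be scaled per treatment group to emulate differing DNA content or
#' chromatin state.
#'
#' @param dna_scale multiplier on the symmetric phosphate stretch amplitude
#' @param amide1_amplitude peak amplitude of the Amide I band
#' @return list of [band_model()] objects
#' @export
default_band_models <- function(dna_scale = 1, amide1_amplitude = 1) {
  list(
    band_model("Amide I",      1655, 55, amide1_amplitude),
    band_model("Amide II",     1545, 50, 0.60 * amide1_amplitude),
    band_model("CH2/CH3 bend", 1455, 40, 0.25 * amide1_amplitude),
    band_model("nu_as PO2-",   1240, 55, 0.22 * amide1_amplitude),
    band_model("nu_s PO2-",    1052, 45, 0.30 * amide1_amplitude * dna_scale)
  )
}

#' Evaluate a sum of Gaussian bands on a wavenumber grid
#'
#' @param bands list of [band_model()] objects (may be empty)
#' @param wavenumbers strictly monotonic wavenumber grid, cm^-1
#' @param baseline constant absorbance offset added to every sample
#' @return absorbance vector of length `length(wavenumbers)`
#' @export
#' @examples
#' wn <- seq(1000, 1800, by = 4)
#' s <- simulate_spectrum(default_band_models(), wn)
simulate_spectrum <- function(bands, wavenumbers, baseline = 0) {
  d <- diff(wavenumbers)
  if (length(wavenumbers) < 2L || !(all(d > 0) || all(d < 0))) {
    stopf("wavenumber grid must be strictly monotonic")
  }
  rng <- range(wavenumbers)
  y <- rep(baseline, length(wavenumbers))
  for (b in bands) {
    if (b$center < rng[1] || b$center > rng[2]) {
      stopf("band '%s' centre %g cm^-1 lies outside the grid [%g, %g]",
            b$name, b$center, rng[1], rng[2], class = "chromamech_band_error")
    }
    # Gaussian with FWHM parameterisation: value amplitude/2 at center +/- width/2
    y <- y + b$amplitude * exp(-4 * log(2) * ((wavenumbers - b$center) / b$width)^2)
  }
  y
}

#' Specification of a synthetic hyperspectral cube
#'
#' Defaults mirror the acquisition conditions the analysis is designed for:
#' 1.1 um pixels and a 4 cm^-1 wavenumber step over the fingerprint region.
#'
#' @param shape image shape in pixels, `c(rows, cols)`
#' @param pixel_size_um pixel edge length, um
#' @param wavenumbers wavenumber grid, cm^-1; must span at least
#'   `[1000, 1800]` so the fingerprint-region analysis applies
#' @param n_cells number of cells to plant
#' @param radius_range_um uniform sampling range for cell radii, um
#' @param groups named list of band-model lists, one per treatment group;
#'   cells are assigned to groups cyclically in planting order
#' @param noise_sd standard deviation of additive i.i.d. Gaussian absorbance
#'   noise per voxel
#' @param background constant background absorbance
#' @param clearance_um minimum free space between cell rims (cells never touch)
#' @param seed integer seed making generation reproducible
#' @return a `cube_spec` object
#' @export
cube_spec <- function(shape = c(128L, 128L),
                      pixel_size_um = 1.1,
                      wavenumbers = seq(1000, 1800, by = 4),
                      n_cells = 30L,
                      radius_range_um = c(5, 7.5),
                      groups = list(control = default_band_models()),
                      noise_sd = 0.02,
                      background = 0,
                      clearance_um = 2,
                      seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 8L), pixel_size_um > 0,
            n_cells >= 0L, length(radius_range_um) == 2L,
            radius_range_um[1] <= radius_range_um[2],
            noise_sd >= 0, length(groups) >= 1L)
  if (min(wavenumbers) > 1000 || max(wavenumbers) < 1800) {
    stopf("wavenumber grid [%g, %g] must span at least [1000, 1800] cm^-1",
          min(wavenumbers), max(wavenumbers))
  }
  if (radius_range_um[1] / pixel_size_um < 2) {
    stopf("minimum cell radius %g um is below 2 pixels at %g um/pixel",
          radius_range_um[1], pixel_size_um)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  structure(
    list(shape = as.integer(shape), pixel_size_um = pixel_size_um,
         wavenumbers = wavenumbers, n_cells = as.integer(n_cells),
         radius_range_um = radius_range_um, groups = groups,
         noise_sd = noise_sd, background = background,
         clearance_um = clearance_um, seed = seed),
    class = "cube_spec"
  )
}

#' Generate a synthetic hyperspectral cube with ground truth
#'
#' Plants `n_cells` non-touching disks, assigns them cyclically to the
#' treatment groups, fills each cell's pixels with its group's band-model
#' spectrum and background pixels with the background level, then adds
#' i.i.d. Gaussian noise. The same spec (including seed) always produces an
#' identical cube.
#'
#' @param spec a [cube_spec()] object
#' @return list with elements `cube` (a [spectral_cube()]) and `truth`, a
#'   list holding `labels` (integer mask, 0 = background), `cells`
#'   (data frame: `cell_id`, `group`, centre and radius in pixels and um)
#'   and `spectra` (matrix of noise-free per-cell spectra, one row per cell)
#' @export
generate_cube <- function(spec) {
  stopifnot(inherits(spec, "cube_spec"))
  with_seed(spec$seed, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    nb <- length(spec$wavenumbers)
    radii_px <- stats::runif(spec$n_cells,
                             spec$radius_range_um[1], spec$radius_range_um[2]) /
      spec$pixel_size_um
    clearance_px <- spec$clearance_um / spec$pixel_size_um

    centers <- matrix(numeric(0), 0, 2)
    max_tries <- 200L * max(1L, spec$n_cells)
    tries <- 0L
    i <- 1L
    while (i <= spec$n_cells) {
      if (tries >= max_tries) {
        stopf("could not place %d non-touching cells in a %dx%d frame after %d tries",
              spec$n_cells, nr, nc, max_tries,
              class = "chromamech_placement_error")
      }
      tries <- tries + 1L
      r <- radii_px[i]
      cand <- c(stats::runif(1, r + 1, nr - r), stats::runif(1, r + 1, nc - r))
      ok <- TRUE
      if (i > 1L) {
        dist <- sqrt(rowSums((centers - matrix(cand, i - 1L, 2, byrow = TRUE))^2))
        ok <- all(dist >= radii_px[seq_len(i - 1L)] + r + clearance_px)
      }
      if (ok) {
        centers <- rbind(centers, cand)
        i <- i + 1L
      }
    }

    labels <- matrix(0L, nr, nc)
    if (spec$n_cells > 0L) {
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (k in seq_len(spec$n_cells)) {
        inside <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2 <= radii_px[k]^2
        labels[inside] <- k
      }
    }

    group_names <- names(spec$groups)
    group_of <- if (spec$n_cells > 0L) {
      group_names[((seq_len(spec$n_cells) - 1L) %% length(group_names)) + 1L]
    } else character(0)
    group_spectra <- vapply(spec$groups, simulate_spectrum,
                            numeric(nb), wavenumbers = spec$wavenumbers)

    # assemble as an (npix x nbands) matrix, then reshape
    mat <- matrix(spec$background, nr * nc, nb)
    for (k in seq_len(spec$n_cells)) {
      idx <- which(labels == k)
      mat[idx, ] <- matrix(group_spectra[, group_of[k]], length(idx), nb,
                           byrow = TRUE)
    }
    if (spec$noise_sd > 0) {
      mat <- mat + stats::rnorm(length(mat), sd = spec$noise_sd)
    }
    cube <- spectral_cube(array(mat, dim = c(nr, nc, nb)),
                          spec$wavenumbers, spec$pixel_size_um)

    cells <- data.frame(
      cell_id = seq_len(spec$n_cells),
      group = group_of,
      row_px = if (spec$n_cells) centers[, 1] else numeric(0),
      col_px = if (spec$n_cells) centers[, 2] else numeric(0),
      radius_px = radii_px,
      radius_um = radii_px * spec$pixel_size_um,
      stringsAsFactors = FALSE
    )
    truth <- list(
      labels = labels,
      cells = cells,
      spectra = t(group_spectra)[group_of, , drop = FALSE],
      wavenumbers = spec$wavenumbers
    )
    list(cube = cube, truth = truth)
  })
}

#' Simulate per-cell spectra for treatment groups
#'
#' Draws `n_cells` spectra per group directly (bypassing the imaging and
#' segmentation stages) for experiments on the spectral-metrics stage alone.
#' Each cell's spectrum is its group's band-model sum plus i.i.d. Gaussian
#' noise at every wavenumber. `noise_sd` is the per-voxel absorbance noise
#' (the same quantity as in [cube_spec()]); because a cell's spectrum in the
#' full pipeline is the average over its segmented pixels, the per-cell
#' spectral noise is `noise_sd / sqrt(pixels_per_cell)`.
#'
#' @param groups named list of band-model lists
#' @param n_cells cells per group
#' @param wavenumbers wavenumber grid, cm^-1
#' @param noise_sd per-voxel Gaussian noise standard deviation (absorbance)
#' @param pixels_per_cell pixels averaged into one cell spectrum (about 100
#'   for a 12.5 um cell at 1.1 um pixels); set to 1 for raw per-voxel noise
#' @param seed integer seed, or `NULL` to use the current RNG state
#' @return a [cell_spectra()] object with a `group` column in its metadata
#' @export
simulate_cell_spectra <- function(groups, n_cells = 50L,
                                  wavenumbers = seq(1000, 1800, by = 4),
                                  noise_sd = 0.1, pixels_per_cell = 100L,
                                  seed = NULL) {
  stopifnot(length(groups) >= 1L, n_cells >= 1L)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  stopifnot(pixels_per_cell >= 1)
  sd_cell <- noise_sd / sqrt(pixels_per_cell)
  with_seed(seed, {
    nb <- length(wavenumbers)
    total <- n_cells * length(groups)
    abs_mat <- matrix(0, total, nb)
    group <- character(total)
    row <- 1L
    for (g in names(groups)) {
      base <- simulate_spectrum(groups[[g]], wavenumbers)
      for (i in seq_len(n_cells)) {
        abs_mat[row, ] <- base + stats::rnorm(nb, sd = sd_cell)
        group[row] <- g
        row <- row + 1L
      }
    }
    cell_spectra(
      wavenumbers = wavenumbers,
      absorbance = abs_mat,
      cell_id = seq_len(total),
      group = group
    )
  })
}
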