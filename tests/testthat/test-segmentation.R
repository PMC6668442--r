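# Chemical images, Otsu+watershed segmentation, per-cell spectrum extraction.

test_that("chemical_image reduces uniform and planted cubes correctly", {
  wn <- seq(1000, 1800, 8)
  # spatially uniform cube -> constant image
  arr <- array(rep(gauss_peak(wn, 1655, 1, 50), each = 12 * 10),
               dim = c(12, 10, length(wn)))
  cube <- spectral_cube(arr, wn, 1.1)
  img <- chemical_image(cube)
  expect_equal(diff(range(img$values)), 0)
  expect_equal(img$values[1, 1], max(gauss_peak(wn, 1655, 1, 50)))

  # noiseless planted cell: in-cell Amide I peak max 1, background 0
  gen <- generate_cube(cube_spec(shape = c(48, 48), n_cells = 1,
                                 noise_sd = 0, seed = 2))
  ci <- chemical_image(gen$cube)
  in_cell <- gen$truth$labels == 1
  expect_equal(max(ci$values[in_cell]), 1, tolerance = 1e-3)
  expect_true(all(ci$values[!in_cell] == 0))
})

test_that("chemical_image equals a brute-force per-pixel oracle", {
  set.seed(42)
  wn <- seq(1000, 1800, 16)
  arr <- array(rnorm(20 * 15 * length(wn)), dim = c(20, 15, length(wn)))
  cube <- spectral_cube(arr, wn, 1)
  band <- c(1200, 1400)
  img <- chemical_image(cube, band)
  idx <- which(wn >= band[1] & wn <= band[2])
  for (i in seq_len(20)) {
    for (j in seq_len(15)) {
      expect_identical(img$values[i, j], max(arr[i, j, idx]))
    }
  }
  # band-reduction bounds: never above the global max, never below the
  # in-band minimum
  expect_lte(max(img$values), max(arr))
  expect_gte(min(img$values), min(arr[, , idx]))
})

test_that("chemical_image validates its band", {
  gen <- generate_cube(cube_spec(shape = c(24, 24), n_cells = 1,
                                 noise_sd = 0, seed = 1))
  expect_error(chemical_image(gen$cube, c(1900, 2000)),
               class = "chromamech_range_error")
  expect_error(chemical_image(gen$cube, c(1700, 1600)))
})

test_that("well-separated planted cells are each recovered with high overlap", {
  gen <- generate_cube(cube_spec(shape = c(96, 96), n_cells = 5,
                                 noise_sd = 0, seed = 4))
  seg <- segment_cells(chemical_image(gen$cube))
  expect_equal(n_segments(seg), 5)
  # match each planted disk to the best segment and demand Jaccard >= 0.8
  for (k in 1:5) {
    planted <- which(gen$truth$labels == k)
    hit <- unique(seg$labels[planted]); hit <- hit[hit > 0]
    expect_length(hit, 1)
    expect_gte(jaccard(planted, which(seg$labels == hit)), 0.8)
  }
})

test_that("watershed splits a pair of disks overlapping by 30% of a radius", {
  img <- two_disk_image(r_px = 6, overlap_frac = 0.3)
  seg <- segment_cells(img, pixel_size_um = 1.1, seed_spacing_um = 8)
  expect_equal(n_segments(seg), 2)
})

test_that("blank noise-only images yield an empty segmentation", {
  set.seed(9)
  img <- matrix(rnorm(64 * 64, sd = 0.01), 64, 64)
  seg <- segment_cells(img, pixel_size_um = 1.1)
  expect_equal(n_segments(seg), 0)
  # empty segmentation propagates to an empty spectra list
  wn <- seq(1000, 1800, 100)
  cube <- spectral_cube(array(rnorm(64 * 64 * length(wn)),
                              c(64, 64, length(wn))), wn, 1.1)
  expect_equal(n_cells(extract_cell_spectra(cube, seg)), 0)
})

test_that("constant images raise a degenerate-threshold error", {
  expect_error(segment_cells(matrix(1, 10, 10), pixel_size_um = 1),
               class = "chromamech_degenerate_image")
})

test_that("extracted means are exact for uniform cells and match a naive loop", {
  # uniform cell: mean equals the planted spectrum exactly
  gen <- generate_cube(cube_spec(shape = c(48, 48), n_cells = 1,
                                 noise_sd = 0, seed = 6))
  seg <- structure(list(labels = gen$truth$labels, params = list()),
                   class = "segmentation")
  cs <- extract_cell_spectra(gen$cube, seg)
  expect_equal(cs$absorbance[1, ],
               simulate_spectrum(default_band_models(), gen$cube$wavenumbers),
               tolerance = 1e-14)
  expect_equal(cs$pixel_count[1], sum(gen$truth$labels == 1))

  # random cube + random mask: agree with the brute-force per-band loop
  set.seed(13)
  wn <- seq(1000, 1800, 40)
  arr <- array(rnorm(30 * 30 * length(wn)), c(30, 30, length(wn)))
  cube <- spectral_cube(arr, wn, 1)
  labels <- matrix(sample(0:3, 900, replace = TRUE), 30, 30)
  seg <- structure(list(labels = labels, params = list()),
                   class = "segmentation")
  cs <- extract_cell_spectra(cube, seg)
  for (k in 1:3) {
    naive <- vapply(seq_along(wn), function(b) {
      slice <- arr[, , b]
      mean(slice[labels == k])
    }, numeric(1))
    expect_equal(cs$absorbance[k, ], naive, tolerance = 1e-12)
  }
})

test_that("extracted spectra are invariant under label permutation", {
  gen <- generate_cube(cube_spec(shape = c(64, 64), n_cells = 3,
                                 noise_sd = 0.05, seed = 8))
  labels <- gen$truth$labels
  seg1 <- structure(list(labels = labels, params = list()),
                    class = "segmentation")
  perm <- c(3L, 1L, 2L)  # relabel 1->3, 2->1, 3->2
  labels2 <- labels
  labels2[labels > 0] <- perm[labels[labels > 0]]
  seg2 <- structure(list(labels = labels2, params = list()),
                    class = "segmentation")
  cs1 <- extract_cell_spectra(gen$cube, seg1)
  cs2 <- extract_cell_spectra(gen$cube, seg2)
  for (k in 1:3) {
    expect_equal(cs2$absorbance[perm[k], ], cs1$absorbance[k, ])
  }
})

test_that("shape mismatches and gappy labels are caught", {
  gen <- generate_cube(cube_spec(shape = c(32, 32), n_cells = 1,
                                 noise_sd = 0, seed = 1))
  seg_bad <- structure(list(labels = matrix(0L, 10, 10), params = list()),
                       class = "segmentation")
  expect_error(extract_cell_spectra(gen$cube, seg_bad),
               class = "chromamech_format_error")
  gappy <- gen$truth$labels * 2L   # labels {0, 2}: 1 missing
  seg_gap <- structure(list(labels = gappy, params = list()),
                       class = "segmentation")
  expect_error(extract_cell_spectra(gen$cube, seg_gap),
               class = "chromamech_internal_error")
})
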