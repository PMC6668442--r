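# Preprocessing chain and trough-baselined peak integration.

wn_full <- seq(900, 3900, by = 4)
wn_fp <- seq(1000, 1800, by = 4)

test_that("crop_fingerprint keeps exactly the requested window", {
  y <- gauss_peak(wn_full, 1655, 1, 50)
  cs <- crop_fingerprint(one_spec(wn_full, y))
  expect_gte(min(cs$wavenumbers), 1000)
  expect_lte(max(cs$wavenumbers), 1800)
  expect_equal(cs$provenance, "crop")

  # already-cropped axes pass through unchanged
  cs2 <- crop_fingerprint(one_spec(wn_fp, gauss_peak(wn_fp, 1655, 1, 50)))
  expect_equal(cs2$wavenumbers, wn_fp)

  # insufficient coverage errors with the actual range
  expect_error(crop_fingerprint(one_spec(seq(1200, 1800, 4), rep(1, 151))),
               "1200", class = "chromamech_coverage_error")
})

test_that("baseline_offset subtracts the anchor value (interpolated off-grid)", {
  y <- gauss_peak(wn_fp, 1655, 1, 50) + 0.30
  cs <- baseline_offset(one_spec(wn_fp, y))
  expect_equal(cs$absorbance[1, wn_fp == 1800], 0)
  expect_equal(cs$absorbance[1, ], y - 0.30)

  # spectrum already zero at the anchor is unchanged
  y0 <- gauss_peak(wn_fp, 1400, 1, 30)
  expect_equal(baseline_offset(one_spec(wn_fp, y0))$absorbance[1, ], y0,
               tolerance = 1e-12)

  # off-grid anchor: matches a hand-computed two-point interpolation
  wn_odd <- c(seq(1000, 1798.6, by = 3.9), 1802.5)
  y_odd <- 0.001 * wn_odd   # a straight line
  anchor <- 1800
  i <- max(which(wn_odd <= anchor))
  frac <- (anchor - wn_odd[i]) / (wn_odd[i + 1] - wn_odd[i])
  expected_offset <- y_odd[i] + frac * (y_odd[i + 1] - y_odd[i])
  cs3 <- baseline_offset(one_spec(wn_odd, y_odd), anchor = anchor)
  expect_equal(cs3$absorbance[1, ], y_odd - expected_offset, tolerance = 1e-12)

  expect_error(baseline_offset(one_spec(wn_fp, y), anchor = 2000),
               class = "chromamech_range_error")
})

test_that("normalize_amide1 scales the window maximum to exactly one", {
  y <- 2 * gauss_peak(wn_fp, 1656, 1, 50)
  cs <- normalize_amide1(one_spec(wn_fp, y))
  idx <- wn_fp >= 1650 & wn_fp <= 1710
  expect_equal(max(cs$absorbance[1, idx]), 1, tolerance = 1e-12)
  expect_equal(cs$absorbance[1, ], y / 2)

  # window max already 1 -> unchanged
  y1 <- gauss_peak(wn_fp, 1656, 1, 50)
  expect_equal(normalize_amide1(one_spec(wn_fp, y1))$absorbance[1, ], y1)

  # all-zero spectrum errors (or flags, when asked to)
  expect_error(normalize_amide1(one_spec(wn_fp, rep(0, length(wn_fp)))),
               class = "chromamech_nonpositive_peak")
  flagged <- normalize_amide1(one_spec(wn_fp, rep(0, length(wn_fp))),
                              on_invalid = "flag")
  expect_equal(flagged$qc_flag, "nonpositive_amide1")
})

test_that("preprocessing is idempotent after the first application", {
  y <- simulate_spectrum(default_band_models(), wn_fp, baseline = 0.2)
  once <- normalize_amide1(baseline_offset(one_spec(wn_fp, y)))
  twice <- normalize_amide1(baseline_offset(once))
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-12)
})

test_that("preprocess_spectra records ordered provenance", {
  cs <- simulate_cell_spectra(list(g = default_band_models()), n_cells = 2,
                              noise_sd = 0, seed = 1,
                              wavenumbers = wn_full)
  proc <- preprocess_spectra(cs)
  expect_equal(proc$provenance, c("crop", "baseline", "normalize"))
  idx <- proc$wavenumbers >= 1650 & proc$wavenumbers <= 1710
  expect_equal(max(proc$absorbance[1, idx]), 1, tolerance = 1e-12)
})

test_that("integrate_peak matches the analytic triangle area and a fine-grid oracle", {
  step <- 0.5
  wn <- seq(1400, 1700, by = step)
  band <- c(1515, 1555)                 # the triangle's exact base
  y <- triangle_peak(wn)
  res <- integrate_peak(wn, y, band, margin = 30)
  expect_equal(res$integral, 20, tolerance = 0.01 * 20)

  # 10x finer grid as the numerical oracle
  wn_fine <- seq(1400, 1700, by = step / 10)
  res_fine <- integrate_peak(wn_fine, triangle_peak(wn_fine), band, margin = 30)
  expect_equal(res$integral, res_fine$integral, tolerance = 0.01 * 20)

  # flat spectrum integrates to zero
  expect_equal(integrate_peak(wn, rep(0.4, length(wn)), band, 30)$integral, 0)
})

test_that("the trough baseline removes a superposed tilted line (<1%)", {
  wn <- seq(1400, 1700, by = 0.5)
  band <- c(1515, 1555)
  base <- integrate_peak(wn, triangle_peak(wn), band, 30)$integral
  for (slope in c(0.002, -0.002)) {
    tilted <- triangle_peak(wn) + 0.5 + slope * (wn - 1400)
    got <- integrate_peak(wn, tilted, band, 30)$integral
    expect_equal(got, base, tolerance = 0.01 * base)
  }
})

test_that("integrate_peak validates its window and reports edge troughs", {
  wn <- seq(1400, 1700, 2)
  y <- triangle_peak(wn)
  expect_error(integrate_peak(wn, y, c(1380, 1420), 30),
               class = "chromamech_range_error")
  res <- integrate_peak(wn, y, c(1515, 1555), 30)
  expect_named(res$at_edge, c("left", "right"))
})

test_that("dna_protein_ratio is 1 for symmetric planted peaks and scales linearly", {
  wn <- seq(950, 1850, by = 1)
  mk <- function(num_amp) {
    gauss_peak(wn, 1052.5, num_amp, 20) + gauss_peak(wn, 1535, 0.5, 20)
  }
  r1 <- dna_protein_ratio(wn, mk(0.5))
  expect_equal(r1$ratio, 1, tolerance = 0.02)

  # doubling the DNA-band amplitude doubles the ratio
  r2 <- dna_protein_ratio(wn, mk(1.0))
  expect_equal(r2$ratio, 2 * r1$ratio, tolerance = 0.02 * 2)

  # zero DNA amplitude -> ratio 0
  r0 <- dna_protein_ratio(wn, mk(0))
  expect_equal(r0$ratio, 0)

  # non-positive denominator is an invalid-cell error
  expect_error(dna_protein_ratio(wn, gauss_peak(wn, 1052.5, 0.5, 20)),
               class = "chromamech_invalid_cell")
})

test_that("the ratio is invariant to rescaling the raw spectrum", {
  cs <- simulate_cell_spectra(list(g = default_band_models()), n_cells = 1,
                              noise_sd = 0.02, seed = 3,
                              wavenumbers = wn_full)
  ref <- compute_ratios(preprocess_spectra(cs))$ratio
  for (c_scale in c(0.1, 3, 42)) {
    scaled <- cs
    scaled$absorbance <- cs$absorbance * c_scale
    got <- compute_ratios(preprocess_spectra(scaled))$ratio
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("the ratio increases monotonically with the DNA-band amplitude", {
  scales <- c(0.5, 0.75, 1, 1.25, 1.5)
  ratios <- vapply(scales, function(s) {
    cs <- simulate_cell_spectra(list(g = default_band_models(dna_scale = s)),
                                n_cells = 1, noise_sd = 0, seed = 1)
    compute_ratios(preprocess_spectra(cs))$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("three noisy groups recover the planted DNA ordering and significance", {
  groups <- list(s_like = default_band_models(dna_scale = 0.7),
                 control = default_band_models(dna_scale = 1.0),
                 g2m_like = default_band_models(dna_scale = 1.4))
  cs <- simulate_cell_spectra(groups, n_cells = 50, noise_sd = 0.1, seed = 21)
  ratios <- compute_ratios(preprocess_spectra(cs))
  m <- tapply(ratios$ratio, ratios$group, mean, na.rm = TRUE)
  expect_lt(m[["s_like"]], m[["control"]])
  expect_lt(m[["control"]], m[["g2m_like"]])
  cmp <- compare_all(ratios$ratio, ratios$group, reference = "control",
                     metric = "dna_protein_ratio")
  expect_true(all(cmp$p <= 0.001))
})
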