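# Shared fixture builders and independent oracles.

# Gaussian band profile with FWHM parameterisation (mirrors the generator's
# definition; used to build spectra independently of simulate_spectrum).
gauss_peak <- function(wn, center, amplitude, fwhm) {
  amplitude * exp(-4 * log(2) * ((wn - center) / fwhm)^2)
}

# Symmetric triangular peak of height `h` and base width `base` centred at
# `center`, zero elsewhere.
triangle_peak <- function(wn, center = 1535, h = 1, base = 40) {
  half <- base / 2
  pmax(h * (1 - abs(wn - center) / half), 0)
}

# Wrap a single spectrum as a one-cell cell_spectra object.
one_spec <- function(wn, y, id = 1L) {
  cell_spectra(wn, matrix(y, nrow = 1), id)
}

# Jaccard overlap of two pixel index sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Exhaustive two-sided permutation p-value for the difference in means
# (all ways of relabelling the pooled values; feasible for n <= 8).
perm_p_value <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  splits <- utils::combn(length(pooled), nx)
  stat <- apply(splits, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  mean(stat >= obs - 1e-12)
}

# Render a two-disk image with centres `sep_frac * r` short of full
# separation (overlap expressed as a fraction of the radius).
two_disk_image <- function(r_px = 6, overlap_frac = 0.3, shape = c(64, 96),
                           value = 1) {
  img <- matrix(0, shape[1], shape[2])
  d <- (2 - overlap_frac) * r_px
  c1 <- c(shape[1] / 2, shape[2] / 2 - d / 2)
  c2 <- c(shape[1] / 2, shape[2] / 2 + d / 2)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  img[(rows - c1[1])^2 + (cols - c1[2])^2 <= r_px^2] <- value
  img[(rows - c2[1])^2 + (cols - c2[2])^2 <= r_px^2] <- value
  img
}
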