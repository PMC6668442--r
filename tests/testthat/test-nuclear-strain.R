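# Detection, tracking, region assignment and strain computation.

geom <- channel_geometry()

test_that("threshold_li matches the minimum-cross-entropy reference values", {
  # expected values computed independently with scikit-image's threshold_li
  # on the same deterministic fixtures
  ij <- 0:63
  img1 <- outer(ij, ij, function(i, j) {
    0.1 + 0.8 * exp(-(((i - 32)^2 + (j - 32)^2) / 120)^2)
  })
  expect_equal(threshold_li(img1), 0.19081220264177623, tolerance = 1e-3)

  img2 <- outer(ij, ij, function(i, j) 0.05 + 0.02 * (i / 63))
  img2[21:40, 16:45] <- 0.7
  expect_equal(threshold_li(img2), 0.20368882885111628, tolerance = 1e-3)

  expect_error(threshold_li(matrix(1, 4, 4)),
               class = "chromamech_degenerate_image")
})

test_that("detect_nuclei recovers planted ellipse axes within 0.3 um", {
  gen <- generate_video(video_spec(nuclei_spec(6, 10, 0, 0, y_um = 32),
                                   geom, n_frames = 8))
  obs <- detect_nuclei(gen$frames[[3]], 0.5)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$minor_um, 6, tolerance = 0.3 / 6)
  expect_equal(obs$major_um, 10, tolerance = 0.3 / 10)
  truth <- gen$truth$per_frame
  expect_equal(obs$x_um, truth$cx_um[truth$frame == 3], tolerance = 0.5)
  expect_equal(obs$y_um, 32, tolerance = 0.5)
})

test_that("detect_nuclei handles blank frames and multiple nuclei", {
  expect_equal(nrow(detect_nuclei(matrix(0.02, 40, 40), 0.5)), 0)
  gen <- generate_video(video_spec(
    nuclei_spec(c(6, 7), c(9, 11), y_um = c(16, 48)), geom, n_frames = 4))
  expect_equal(nrow(detect_nuclei(gen$frames[[2]], 0.5)), 2)
})

test_that("a single nucleus yields one trajectory containing every observation", {
  gen <- generate_video(video_spec(nuclei_spec(6, 10, 0, 0, y_um = 32),
                                   geom, n_frames = 20))
  obs <- detect_video(gen$frames, 0.5)
  tr <- link_tracks(obs)
  expect_equal(length(unique(tr$nucleus_id)), 1)
  expect_equal(nrow(tr), nrow(obs))
})

test_that("two parallel nuclei give two trajectories matching ground truth", {
  gen <- generate_video(video_spec(
    nuclei_spec(c(6, 7), c(9, 11), y_um = c(16, 48)), geom, n_frames = 20))
  tr <- link_tracks(detect_video(gen$frames, 0.5))
  expect_equal(length(unique(tr$nucleus_id)), 2)
  # identity check: each trajectory stays in its planted lane
  lanes <- tapply(tr$y_um, tr$nucleus_id, function(y) max(abs(y - mean(y))))
  expect_true(all(lanes < 1))
  means <- sort(as.numeric(tapply(tr$y_um, tr$nucleus_id, mean)))
  expect_equal(means, c(16, 48), tolerance = 0.5)
})

test_that("a dropout of two frames is stitched into a single trajectory", {
  gen <- generate_video(video_spec(nuclei_spec(6, 10, 0, 0, y_um = 32),
                                   geom, n_frames = 20))
  obs <- detect_video(gen$frames, 0.5)
  obs <- obs[!obs$frame %in% c(9, 10), ]      # simulated detection dropout
  tr <- link_tracks(obs, max_gap = 3)
  expect_equal(length(unique(tr$nucleus_id)), 1)
  expect_length(attr(tr, "stitches"), 1)
  # with the gap larger than max_gap the fragments stay separate
  obs2 <- obs[!obs$frame %in% 8:12, ]
  tr2 <- link_tracks(obs2, max_gap = 3)
  expect_equal(length(unique(tr2$nucleus_id)), 2)
})

test_that("region assignment follows the window and margin geometry", {
  g <- channel_geometry(entry_um = 100, region1_window_um = 50,
                        entrance_margin_um = 5)
  tracks <- data.frame(frame = 1:3, nucleus_id = 1L,
                       x_um = c(70, 225, 101),   # 30 um upstream; midpoint; 1 um in
                       y_um = 32, minor_um = 6, major_um = 10)
  out <- assign_regions(tracks, g)
  expect_equal(out$region, c("region1", "region2", "excluded"))
})

test_that("compute_strain reproduces the worked strain formulas", {
  mk_tracks <- function(minor1, minor2) {
    data.frame(
      frame = 1:8, nucleus_id = 1L,
      x_um = c(30, 48, 66, 84, 120, 150, 180, 210),
      y_um = 32,
      minor_um = c(rep(minor1, 4), rep(minor2, 4)),
      major_um = c(rep(12, 4), rep(13, 4))
    )
  }
  g <- channel_geometry(entry_um = 100, region1_window_um = 80,
                        entrance_margin_um = 5)
  # a = 10, a' = 10 -> S_T = 0
  r <- compute_strain(assign_regions(mk_tracks(10, 10), g), g)
  expect_identical(r$S_T, 0)
  # a = 8, a' = 10 -> S_T = +0.25, auxetic
  r <- compute_strain(assign_regions(mk_tracks(8, 10), g), g)
  expect_identical(r$S_T, 0.25)
  expect_true(r$auxetic)
  expect_false(r$small_nucleus)   # a = 8 is not strictly below the 8 um width
  # a = 10, a' = 8 -> S_T = -0.2, not auxetic, not small
  r <- compute_strain(assign_regions(mk_tracks(10, 8), g), g)
  expect_identical(r$S_T, -0.2)
  expect_false(r$auxetic)
  expect_false(r$small_nucleus)
  # S_A from the major axes: (13 - 12)/12
  expect_equal(r$S_A, 1 / 12)
})

test_that("region means agree with a brute-force re-average and stay disjoint", {
  gen <- generate_video(video_spec(nuclei_spec(6.5, 10, 0.2, 0.1, y_um = 32),
                                   geom, n_frames = 40))
  tr <- assign_regions(link_tracks(detect_video(gen$frames, 0.5)), geom)
  expect_false(any(tr$region == "region1" & tr$region == "region2"))
  res <- compute_strain(tr, geom)
  expect_equal(res$a_um, mean(tr$minor_um[tr$region == "region1"]))
  expect_equal(res$a_prime_um, mean(tr$minor_um[tr$region == "region2"]))
  expect_equal(res$S_T, (res$a_prime_um - res$a_um) / res$a_um)
})

test_that("trajectories with too few region observations are excluded with a reason", {
  g <- channel_geometry(entry_um = 100)
  tracks <- data.frame(frame = 1:5, nucleus_id = 1L,
                       x_um = c(30, 48, 120, 150, 180), y_um = 32,
                       minor_um = 6, major_um = 10)
  res <- compute_strain(assign_regions(tracks, g), g, min_obs = 3)
  expect_equal(res$exclusion_reason, "too_few_region1_observations")
  expect_true(is.na(res$S_T))
})

test_that("strain_table filters the small-nuclei subset by channel width", {
  res <- data.frame(
    nucleus_id = 1:3, n_region1 = 5, n_region2 = 5,
    a_um = c(6, 9, 7.9), a_prime_um = c(6.6, 8.5, 8.2),
    b_um = 10, b_prime_um = 11,
    S_T = c(0.1, -0.055, 0.038), S_A = 0.1,
    auxetic = c(TRUE, FALSE, TRUE), small_nucleus = c(TRUE, FALSE, TRUE),
    speed_um_s = 550, exclusion_reason = ""
  )
  tab <- strain_table(res, channel_width_um = 8)
  expect_equal(tab$small_nuclei$nucleus_id, c(1, 3))
  expect_equal(nrow(tab$scatter), 3)
  expect_named(tab$scatter, c("minor_axis_um", "S_T"))
  expect_error(strain_table(res[0, ]), class = "chromamech_empty_results")
})
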