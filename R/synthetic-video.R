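# Synthetic microfluidic translocation videos with full ground truth.
#
# Hoechst-stained nuclei are rendered as filled ellipses with a smooth
# (super-Gaussian) intensity falloff, translating at constant speed along the
# flow axis. Inside the constriction channel the minor/major axes take their
# planted strained values a*(1+S_T) and b*(1+S_A); the switch happens over a
# two-frame linear ramp at the entrance (and symmetrically at the exit), since
# an instantaneous shape jump would be unphysical.

#' Describe the nuclei to plant in a synthetic video
#'
#' @param minor_um,major_um pre-channel minor/major axes, um
#' @param s_t,s_a planted transverse/axial strain (dimensionless)
#' @param speed_um_s translocation speed, um/s (study conditions: ~550 um/s)
#' @param entry_frame first frame (1-based) in which the nucleus appears
#' @param y_um transverse centre position, um (one channel lane per nucleus)
#' @param x0_um flow-axis centre at `entry_frame`, um
#' @return data frame, one row per nucleus
#' @export
nuclei_spec <- function(minor_um, major_um, s_t = 0, s_a = 0,
                        speed_um_s = 550, entry_frame = 1L,
                        y_um = NULL, x0_um = NULL) {
  n <- max(length(minor_um), length(major_um), length(s_t), length(s_a))
  data.frame(
    nucleus_id = seq_len(n),
    minor_um = rep_len(minor_um, n), major_um = rep_len(major_um, n),
    s_t = rep_len(s_t, n), s_a = rep_len(s_a, n),
    speed_um_s = rep_len(speed_um_s, n),
    entry_frame = rep_len(as.integer(entry_frame), n),
    y_um = if (is.null(y_um)) rep(NA_real_, n) else rep_len(y_um, n),
    x0_um = if (is.null(x0_um)) rep(NA_real_, n) else rep_len(x0_um, n)
  )
}

#' Specification of a synthetic translocation video
#'
#' Defaults mirror the study conditions: 30 frames/s and ~0.55 mm/s
#' translocation speed through an 8 um-wide, 250 um-long channel.
#'
#' @param nuclei a [nuclei_spec()] data frame
#' @param geometry a [channel_geometry()]
#' @param frame_shape frame shape in pixels, `c(rows, cols)`; flow runs along
#'   the columns
#' @param pixel_size_um pixel edge length, um
#' @param n_frames number of frames
#' @param frame_interval_s time between frames, s
#' @param noise_sd fluorescence noise standard deviation (fraction of the
#'   16-bit range)
#' @param background constant background intensity
#' @param intensity peak nucleus intensity
#' @param sharpness super-Gaussian edge order: intensity falls as
#'   `exp(-(r/r0)^sharpness)` in normalized radius; the default gives a sub-pixel
#'   edge transition (about half a point-spread-function
#'   width for a high-NA objective at 0.5 um pixels)
#' @param seed integer seed for the noise
#' @return a `video_spec` object
#' @export
video_spec <- function(nuclei,
                       geometry = channel_geometry(),
                       frame_shape = c(128L, 896L),
                       pixel_size_um = 0.5,
                       n_frames = 40L,
                       frame_interval_s = 1 / 30,
                       noise_sd = 0,
                       background = 0.02,
                       intensity = 0.8,
                       sharpness = 40,
                       seed = 1L) {
  stopifnot(is.data.frame(nuclei), nrow(nuclei) >= 0L,
            inherits(geometry, "channel_geometry"),
            length(frame_shape) == 2L, pixel_size_um > 0, n_frames >= 1L,
            frame_interval_s > 0, noise_sd >= 0, sharpness >= 1)
  if (nrow(nuclei) > 0L) {
    if (any(nuclei$s_t <= -1)) {
      stopf("planted transverse strain must exceed -1")
    }
    if (any(nuclei$speed_um_s <= 0)) stopf("nucleus speed must be positive")
    in_channel_minor <- nuclei$minor_um * (1 + nuclei$s_t)
    if (any(in_channel_minor > 2 * geometry$width_um)) {
      stopf("planted in-channel minor axis %.1f um exceeds twice the channel width (%g um): unphysical",
            max(in_channel_minor), geometry$width_um,
            class = "chromamech_unphysical_spec")
    }
    # default lanes: spread nuclei across the frame height
    h_um <- frame_shape[1] * pixel_size_um
    lane <- which(is.na(nuclei$y_um))
    if (length(lane)) {
      nuclei$y_um[lane] <- h_um * (seq_along(lane)) / (length(lane) + 1)
    }
    start <- which(is.na(nuclei$x0_um))
    if (length(start)) {
      nuclei$x0_um[start] <- geometry$entry_um - geometry$region1_window_um - 10
    }
  }
  spec <- structure(
    list(nuclei = nuclei, geometry = geometry,
         frame_shape = as.integer(frame_shape),
         pixel_size_um = pixel_size_um, n_frames = as.integer(n_frames),
         frame_interval_s = frame_interval_s, noise_sd = noise_sd,
         background = background, intensity = intensity,
         sharpness = sharpness, seed = seed),
    class = "video_spec"
  )
  check_no_overlap(spec)
  spec
}

# True axes of one nucleus at flow position x: two-frame linear ramps at the
# channel entrance and exit between undeformed and planted strained axes.
true_axes_at <- function(x, nuc, geom, ramp_um) {
  f_in <- pmin(pmax((x - geom$entry_um) / ramp_um, 0), 1)
  f_out <- pmin(pmax((geom$exit_um + ramp_um - x) / ramp_um, 0), 1)
  f <- pmin(f_in, f_out)
  list(minor = nuc$minor_um * (1 + f * nuc$s_t),
       major = nuc$major_um * (1 + f * nuc$s_a))
}

nucleus_positions <- function(spec, frame) {
  nuc <- spec$nuclei
  active <- nuc$entry_frame <= frame
  nuc <- nuc[active, , drop = FALSE]
  if (nrow(nuc) == 0L) return(nuc)
  dt <- (frame - nuc$entry_frame) * spec$frame_interval_s
  nuc$x_um <- nuc$x0_um + nuc$speed_um_s * dt
  nuc
}

check_no_overlap <- function(spec) {
  for (f in seq_len(spec$n_frames)) {
    nuc <- nucleus_positions(spec, f)
    if (nrow(nuc) < 2L) next
    ramp <- 2 * nuc$speed_um_s * spec$frame_interval_s
    for (i in seq_len(nrow(nuc) - 1L)) {
      for (j in (i + 1L):nrow(nuc)) {
        ax_i <- true_axes_at(nuc$x_um[i], nuc[i, ], spec$geometry, ramp[i])
        ax_j <- true_axes_at(nuc$x_um[j], nuc[j, ], spec$geometry, ramp[j])
        d <- sqrt((nuc$x_um[i] - nuc$x_um[j])^2 + (nuc$y_um[i] - nuc$y_um[j])^2)
        if (d < (ax_i$major + ax_j$major) / 2) {
          stopf("nuclei %d and %d overlap in frame %d",
                nuc$nucleus_id[i], nuc$nucleus_id[j], f)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic translocation video with ground truth
#'
#' @param spec a [video_spec()]
#' @return list with `frames` (list of matrices in `[0, 1]`, one per frame)
#'   and `truth`: `per_frame` (data frame `frame, nucleus_id, cx_um, cy_um,
#'   minor_um, major_um` of true instantaneous values) and `nuclei` (planted
#'   pre-channel axes `a`, `b`, in-channel plateau axes `a_prime`, `b_prime`,
#'   and planted strains)
#' @export
generate_video <- function(spec) {
  stopifnot(inherits(spec, "video_spec"))
  with_seed(spec$seed, {
    nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
    px <- spec$pixel_size_um
    xs <- (seq_len(nc) - 0.5) * px   # flow axis (columns)
    ys <- (seq_len(nr) - 0.5) * px   # transverse axis (rows)
    frames <- vector("list", spec$n_frames)
    gt <- vector("list", spec$n_frames)

    for (f in seq_len(spec$n_frames)) {
      img <- matrix(spec$background, nr, nc)
      nuc <- nucleus_positions(spec, f)
      rows <- NULL
      for (k in seq_len(nrow(nuc))) {
        ramp <- 2 * nuc$speed_um_s[k] * spec$frame_interval_s
        ax <- true_axes_at(nuc$x_um[k], nuc[k, ], spec$geometry, ramp)
        sx <- ax$major / 2; sy <- ax$minor / 2
        # render only inside a bounding box around the ellipse
        jr <- which(abs(xs - nuc$x_um[k]) <= 1.6 * sx)
        ir <- which(abs(ys - nuc$y_um[k]) <= 1.6 * sy)
        if (length(jr) && length(ir)) {
          qx <- ((xs[jr] - nuc$x_um[k]) / sx)^2
          qy <- ((ys[ir] - nuc$y_um[k]) / sy)^2
          q <- outer(qy, qx, `+`)
          img[ir, jr] <- img[ir, jr] +
            spec$intensity * exp(-q^(spec$sharpness / 2))
        }
        rows <- rbind(rows, data.frame(
          frame = f, nucleus_id = nuc$nucleus_id[k],
          cx_um = nuc$x_um[k], cy_um = nuc$y_um[k],
          minor_um = ax$minor, major_um = ax$major
        ))
      }
      if (spec$noise_sd > 0) {
        img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
      }
      frames[[f]] <- pmin(pmax(img, 0), 1)
      gt[[f]] <- rows
    }

    nuc <- spec$nuclei
    truth_nuclei <- data.frame(
      nucleus_id = nuc$nucleus_id,
      a_um = nuc$minor_um, b_um = nuc$major_um,
      a_prime_um = nuc$minor_um * (1 + nuc$s_t),
      b_prime_um = nuc$major_um * (1 + nuc$s_a),
      s_t = nuc$s_t, s_a = nuc$s_a,
      speed_um_s = nuc$speed_um_s, entry_frame = nuc$entry_frame,
      y_um = nuc$y_um
    )
    list(frames = frames,
         truth = list(per_frame = do.call(rbind, gt), nuclei = truth_nuclei))
  })
}

#' Write per-frame ground truth as CSV
#' @param truth the `truth` element of a [generate_video()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ground_truth_csv <- function(truth, path) {
  utils::write.csv(truth$per_frame, path, row.names = FALSE)
  invisible(path)
}
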