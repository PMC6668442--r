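# Nucleus detection, tracking and strain analysis for constriction videos.
#
# Nuclei are segmented per frame by Li minimum-cross-entropy thresholding,
# measured as moment-equivalent ellipses, tracked by greedy nearest-neighbour
# linking with automated gap closing, assigned to region 1 (pre-channel) or
# region 2 (inside the channel), and summarised as transverse strain
# S_T = (a' - a)/a and axial strain S_A = (b' - b)/b, where a/b are region-1
# mean minor/major axes and a'/b' the region-2 means. A positive transverse
# strain marks auxetic (cross-section-expanding) behaviour.

#' Microfluidic channel geometry
#'
#' Internally the flow axis is treated as +x; vertical-flow videos are
#' rotated on ingestion.
#'
#' @param entry_um channel entrance coordinate along the flow axis, um
#' @param width_um channel width, um (square cross-section side)
#' @param length_um channel length, um
#' @param flow_axis `"horizontal"` (flow along image columns) or `"vertical"`
#' @param region1_window_um extent of the pre-channel window upstream of the
#'   entrance used for region-1 means, um
#' @param entrance_margin_um exclusion margin on both sides of the entrance
#'   (and inside the exit) where the nucleus is partially deformed, um
#' @return a `channel_geometry` object with `exit_um = entry_um + length_um`
#' @export
channel_geometry <- function(entry_um = 100, width_um = 8, length_um = 250,
                             flow_axis = c("horizontal", "vertical"),
                             region1_window_um = 80,
                             entrance_margin_um = 5) {
  flow_axis <- match.arg(flow_axis)
  stopifnot(width_um > 0, length_um > 0, region1_window_um > 0,
            entrance_margin_um >= 0)
  if (entrance_margin_um >= region1_window_um) {
    stopf("entrance margin (%g um) leaves no region-1 window (%g um)",
          entrance_margin_um, region1_window_um)
  }
  if (2 * entrance_margin_um >= length_um) {
    stopf("entrance margin (%g um) leaves no region-2 span in a %g um channel",
          entrance_margin_um, length_um)
  }
  structure(
    list(entry_um = entry_um, exit_um = entry_um + length_um,
         width_um = width_um, length_um = length_um, flow_axis = flow_axis,
         region1_window_um = region1_window_um,
         entrance_margin_um = entrance_margin_um),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> %g um wide x %g um long, entry at %g um (%s flow)\n",
    x$width_um, x$length_um, x$entry_um, x$flow_axis))
  invisible(x)
}

#' Li minimum-cross-entropy threshold
#'
#' Iterates Li & Tam's fixed-point update on the foreground/background class
#' means until convergence, starting from the image mean.
#'
#' @param x numeric vector, matrix or array of intensities
#' @param max_iter iteration cap
#' @return the threshold, on the intensity scale of `x`
#' @export
threshold_li <- function(x, max_iter = 100L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) {
    stopf("constant image has no threshold", class = "chromamech_degenerate_image")
  }
  v <- v - rng[1]                       # logs need non-negative support
  eps <- diff(rng) * 1e-12
  tol <- diff(rng) / 2^16
  t_next <- mean(v)
  t_curr <- -2 * tol
  iter <- 0L
  while (abs(t_next - t_curr) > tol && iter < max_iter) {
    t_curr <- t_next
    fore <- v > t_curr
    mean_fore <- max(mean(v[fore]), eps)
    mean_back <- max(mean(v[!fore]), eps)
    t_next <- (mean_back - mean_fore) / (log(mean_back) - log(mean_fore))
    iter <- iter + 1L
  }
  t_next + rng[1]
}

# Moment-equivalent ellipse axes (full lengths, um) of a pixel set.
# Intensity-weighted covariance of pixel centres plus the 1/12 per-pixel
# variance correction; axis length = 4*sqrt(eigenvalue), exact for a solid
# ellipse. Weighting by intensity suppresses the jagged-boundary noise of a
# binary mask on small (~10 px) objects.
equivalent_ellipse <- function(rows, cols, pixel_size_um, weights = NULL) {
  x <- (cols - 0.5) * pixel_size_um
  y <- (rows - 0.5) * pixel_size_um
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  corr <- pixel_size_um^2 / 12
  vx <- sum(w * (x - mx)^2) + corr
  vy <- sum(w * (y - my)^2) + corr
  vxy <- sum(w * (x - mx) * (y - my))
  tr <- vx + vy
  disc <- sqrt(max((vx - vy)^2 + 4 * vxy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  list(cx = mx, cy = my, major = 4 * sqrt(max(l1, 0)),
       minor = 4 * sqrt(max(l2, 0)))
}

#' Detect nuclei in one fluorescence frame
#'
#' Li threshold, connected components, intensity-weighted moment-equivalent
#' ellipse per component. Components smaller than `min_area_um2` are dropped.
#'
#' @param frame 2-D intensity matrix
#' @param pixel_size_um pixel edge length, um
#' @param min_area_um2 minimum component area, um^2
#' @return data frame, one row per nucleus: centroid (`x_um` along columns,
#'   `y_um` along rows), `minor_um`, `major_um`, `area_um2`,
#'   `mean_intensity`; empty for blank frames
#' @export
detect_nuclei <- function(frame, pixel_size_um, min_area_um2 = 4) {
  stopifnot(is.matrix(frame), pixel_size_um > 0)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      minor_um = numeric(0), major_um = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  if (diff(range(frame)) == 0) return(empty)
  thr <- threshold_li(frame)
  mask <- frame > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(frame), ncol(frame))
  out <- empty
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    area <- length(idx) * pixel_size_um^2
    if (area < min_area_um2) next
    rows <- ((idx - 1L) %% nrow(frame)) + 1L
    cols <- ((idx - 1L) %/% nrow(frame)) + 1L
    ell <- equivalent_ellipse(rows, cols, pixel_size_um,
                              weights = frame[idx])
    out <- rbind(out, data.frame(
      x_um = ell$cx, y_um = ell$cy, minor_um = ell$minor,
      major_um = ell$major, area_um2 = area,
      mean_intensity = mean(frame[idx])
    ))
  }
  out
}

#' Detect nuclei in every frame of a video
#'
#' @param frames list of intensity matrices
#' @param pixel_size_um pixel edge length, um
#' @param min_area_um2 minimum component area, um^2
#' @return data frame of per-frame observations with a `frame` column
#' @export
detect_video <- function(frames, pixel_size_um, min_area_um2 = 4) {
  obs <- lapply(seq_along(frames), function(f) {
    d <- detect_nuclei(frames[[f]], pixel_size_um, min_area_um2)
    if (nrow(d)) cbind(frame = f, d) else NULL
  })
  out <- do.call(rbind, obs)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      minor_um = numeric(0), major_um = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  }
  out
}

# 1.5 x mean frame-to-frame nearest-neighbour displacement.
estimate_gating <- function(obs) {
  frames <- sort(unique(obs$frame))
  d <- c()
  for (f in frames[-length(frames)]) {
    a <- obs[obs$frame == f, ]
    b <- obs[obs$frame == f + 1L, ]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    for (i in seq_len(nrow(a))) {
      d <- c(d, min(sqrt((b$x_um - a$x_um[i])^2 + (b$y_um - a$y_um[i])^2)))
    }
  }
  if (length(d) == 0L) return(Inf)
  1.5 * mean(d)
}

#' Link per-frame observations into trajectories
#'
#' Greedy nearest-neighbour assignment between consecutive frames within a
#' gating distance, followed by automated stitching of trajectory fragments:
#' a fragment starting within `max_gap` frames and within
#' `gating x gap` distance of another fragment's end is merged into it.
#' Ties are broken deterministically (smaller track id first).
#'
#' @param obs per-frame observations from [detect_video()]
#' @param gating_um gating distance, um; `NULL` estimates
#'   1.5 x the mean per-frame displacement from the data
#' @param max_gap maximum frame gap closed by stitching
#' @return the observations with a `nucleus_id` column; stitched fragment
#'   ids are recorded in `attr(, "stitches")` and the gating used in
#'   `attr(, "gating_um")`
#' @export
link_tracks <- function(obs, gating_um = NULL, max_gap = 3L) {
  if (nrow(obs) == 0L) {
    obs$nucleus_id <- integer(0)
    return(obs)
  }
  gating_um <- gating_um %||% estimate_gating(obs)
  obs <- obs[order(obs$frame), , drop = FALSE]
  obs$nucleus_id <- NA_integer_
  frames <- sort(unique(obs$frame))
  n_tracks <- 0L
  last_frame <- integer(0)   # per track
  last_x <- numeric(0); last_y <- numeric(0)

  for (f in frames) {
    oi <- which(obs$frame == f)
    active <- which(last_frame == f - 1L)
    if (length(active) && length(oi)) {
      cand <- expand.grid(track = active, o = oi)
      cand$dist <- sqrt((last_x[cand$track] - obs$x_um[cand$o])^2 +
                        (last_y[cand$track] - obs$y_um[cand$o])^2)
      cand <- cand[cand$dist <= gating_um, , drop = FALSE]
      cand <- cand[order(cand$dist, cand$track, cand$o), , drop = FALSE]
      used_t <- integer(0); used_o <- integer(0)
      for (r in seq_len(nrow(cand))) {
        tr <- cand$track[r]; o <- cand$o[r]
        if (tr %in% used_t || o %in% used_o) next
        obs$nucleus_id[o] <- tr
        last_frame[tr] <- f; last_x[tr] <- obs$x_um[o]; last_y[tr] <- obs$y_um[o]
        used_t <- c(used_t, tr); used_o <- c(used_o, o)
      }
    }
    for (o in oi[is.na(obs$nucleus_id[oi])]) {
      n_tracks <- n_tracks + 1L
      obs$nucleus_id[o] <- n_tracks
      last_frame[n_tracks] <- f
      last_x[n_tracks] <- obs$x_um[o]; last_y[n_tracks] <- obs$y_um[o]
    }
  }

  # gap-closing: merge fragments end-to-start
  stitches <- list()
  repeat {
    ids <- sort(unique(obs$nucleus_id))
    ends <- t(vapply(ids, function(id) {
      rows <- obs[obs$nucleus_id == id, ]
      c(first = min(rows$frame), last = max(rows$frame),
        x0 = rows$x_um[which.min(rows$frame)],
        y0 = rows$y_um[which.min(rows$frame)],
        x1 = rows$x_um[which.max(rows$frame)],
        y1 = rows$y_um[which.max(rows$frame)])
    }, numeric(6)))
    best <- NULL
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i == j) next
        gap <- ends[j, "first"] - ends[i, "last"]
        if (gap < 1 || gap > max_gap) next
        d <- sqrt((ends[j, "x0"] - ends[i, "x1"])^2 +
                  (ends[j, "y0"] - ends[i, "y1"])^2)
        if (d > gating_um * gap) next
        score <- d / gap
        if (is.null(best) || score < best$score) {
          best <- list(from = ids[j], into = ids[i], score = score)
        }
      }
    }
    if (is.null(best)) break
    obs$nucleus_id[obs$nucleus_id == best$from] <- best$into
    stitches[[length(stitches) + 1L]] <- c(into = best$into, from = best$from)
  }

  # compact, deterministic renumbering by first frame then transverse position
  ids <- unique(obs$nucleus_id[order(obs$frame, obs$y_um)])
  obs$nucleus_id <- match(obs$nucleus_id, ids)
  attr(obs, "stitches") <- stitches
  attr(obs, "gating_um") <- gating_um
  obs
}

#' Label each observation with its channel region
#'
#' Region 1 is the pre-channel window upstream of the entrance (outside the
#' entrance margin); region 2 is the channel interior away from the entrance
#' and exit margins; everything else is excluded.
#'
#' @param tracks linked observations from [link_tracks()]
#' @param geom a [channel_geometry()]
#' @return `tracks` with a `region` column in
#'   `{"region1", "region2", "excluded"}`
#' @export
assign_regions <- function(tracks, geom) {
  stopifnot(inherits(geom, "channel_geometry"))
  pos <- if (geom$flow_axis == "horizontal") tracks$x_um else tracks$y_um
  region <- rep("excluded", nrow(tracks))
  region[pos >= geom$entry_um - geom$region1_window_um &
         pos <= geom$entry_um - geom$entrance_margin_um] <- "region1"
  region[pos >= geom$entry_um + geom$entrance_margin_um &
         pos <= geom$exit_um - geom$entrance_margin_um] <- "region2"
  tracks$region <- region
  tracks
}

#' Strain and flags from region-mean axes
#'
#' The formula core: transverse strain `S_T = (a' - a)/a` and axial strain
#' `S_A = (b' - b)/b` from the pre-channel means `a`, `b` and in-channel
#' means `a'`, `b'`. A nucleus is auxetic when `S_T > 0` and "small" when
#' its pre-channel minor axis is below the channel width.
#'
#' @param a,a_prime region-1 and region-2 mean minor axes, um
#' @param b,b_prime region-1 and region-2 mean major axes, um (optional)
#' @param channel_width_um channel width, um
#' @return data frame: `S_T`, `S_A`, `auxetic`, `small_nucleus` (vectorized)
#' @export
strain_from_axes <- function(a, a_prime, b = NA_real_, b_prime = NA_real_,
                             channel_width_um = 8) {
  stopifnot(all(a > 0, na.rm = TRUE))
  data.frame(
    S_T = (a_prime - a) / a,
    S_A = (b_prime - b) / b,
    auxetic = (a_prime - a) / a > 0,
    small_nucleus = a < channel_width_um
  )
}

#' Per-nucleus strain from a tracked, region-labelled video
#'
#' For every trajectory with at least `min_obs` observations in each region,
#' computes region-mean axes and the transverse/axial strain. Trajectories
#' failing the observation requirement are kept with an `exclusion_reason`
#' rather than silently dropped.
#'
#' @param tracks region-labelled observations from [assign_regions()]
#' @param geom a [channel_geometry()]
#' @param min_obs minimum observations per region for inclusion
#' @param frame_interval_s frame interval, s (for the per-trajectory speed)
#' @return data frame, one row per trajectory: observation counts, region
#'   means `a_um`, `a_prime_um`, `b_um`, `b_prime_um`, `S_T`, `S_A`,
#'   `auxetic`, `small_nucleus`, `speed_um_s`, `exclusion_reason`
#' @export
compute_strain <- function(tracks, geom, min_obs = 3L,
                           frame_interval_s = 1 / 30) {
  stopifnot(inherits(geom, "channel_geometry"), "region" %in% names(tracks))
  ids <- sort(unique(tracks$nucleus_id))
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$nucleus_id == id, ]
    tr <- tr[order(tr$frame), ]
    r1 <- tr[tr$region == "region1", ]
    r2 <- tr[tr$region == "region2", ]
    speed <- if (nrow(tr) >= 2L) {
      steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / diff(tr$frame)
      mean(steps) / frame_interval_s
    } else NA_real_
    base <- data.frame(
      nucleus_id = id, n_region1 = nrow(r1), n_region2 = nrow(r2),
      a_um = NA_real_, a_prime_um = NA_real_, b_um = NA_real_,
      b_prime_um = NA_real_, S_T = NA_real_, S_A = NA_real_,
      auxetic = NA, small_nucleus = NA, speed_um_s = speed,
      exclusion_reason = "", stringsAsFactors = FALSE
    )
    if (nrow(r1) < min_obs || nrow(r2) < min_obs) {
      base$exclusion_reason <- if (nrow(r1) < min_obs) {
        "too_few_region1_observations"
      } else "too_few_region2_observations"
      return(base)
    }
    base$a_um <- mean(r1$minor_um); base$b_um <- mean(r1$major_um)
    base$a_prime_um <- mean(r2$minor_um); base$b_prime_um <- mean(r2$major_um)
    s <- strain_from_axes(base$a_um, base$a_prime_um, base$b_um,
                          base$b_prime_um, geom$width_um)
    base$S_T <- s$S_T; base$S_A <- s$S_A
    base$auxetic <- s$auxetic; base$small_nucleus <- s$small_nucleus
    base
  })
  do.call(rbind, out)
}

#' Tabulate strain results and the small-nuclei subset
#'
#' @param results data frame from [compute_strain()] (included nuclei only
#'   or mixed; excluded rows are carried through)
#' @param channel_width_um channel width defining "small", um
#' @return a `strain_table`: `table` (all rows), `small_nuclei` (included
#'   nuclei with pre-channel minor axis below the channel width) and
#'   `scatter` (`minor_axis_um`, `S_T` pairs for included nuclei)
#' @export
strain_table <- function(results, channel_width_um = 8) {
  if (is.null(results) || nrow(results) == 0L) {
    stopf("no strain results to tabulate", class = "chromamech_empty_results")
  }
  included <- results[results$exclusion_reason == "" & !is.na(results$S_T), ]
  structure(
    list(table = results,
         small_nuclei = included[included$a_um < channel_width_um, ],
         scatter = data.frame(minor_axis_um = included$a_um,
                              S_T = included$S_T)),
    class = "strain_table"
  )
}

#' @export
print.strain_table <- function(x, ...) {
  cat(sprintf("<strain_table> %d nuclei (%d included, %d small)\n",
              nrow(x$table),
              sum(x$table$exclusion_reason == ""),
              nrow(x$small_nuclei)))
  invisible(x)
}
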