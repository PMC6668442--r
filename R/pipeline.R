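# End-to-end pipelines: simulate -> segment -> ratios -> compare, and
# simulate -> track -> strain -> compare, with config, provenance and
# deterministic outputs.

#' Default run configuration
#'
#' Every analysis parameter with an established default is set here: the
#' band windows, the 1800 cm^-1 offset anchor, the 1710-1650 cm^-1
#' normalization window, the fingerprint region, and the 8 um x 250 um
#' channel geometry. Flags and config files override these values.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    seed = 1L,
    spectral = list(
      simulate = list(
        enabled = TRUE, n_cells = 30L,
        groups = list(control = 1.0),        # group name -> DNA-band scale
        shape = c(128L, 128L), pixel_size_um = 1.1,
        noise_sd = 0.02, radius_range_um = c(5, 7.5)
      ),
      cube_path = NULL, group_map = NULL,
      image_band = c(1625, 1675),
      min_area_um2 = 20, max_area_um2 = 500, seed_spacing_um = 8,
      fingerprint = c(1000, 1800), anchor = 1800,
      norm_window = c(1650, 1710),
      num_band = c(1035, 1070), den_band = c(1490, 1580), margin = 30,
      reference_group = NULL
    ),
    strain = list(
      simulate = list(
        enabled = TRUE,
        groups = list(control = list(n_nuclei = 5L, s_t_mean = -0.1,
                                     s_t_sd = 0.04, s_a_mean = 0.05,
                                     s_a_sd = 0.02,
                                     minor_range_um = c(5, 9),
                                     aspect = 1.5, speed_um_s = 550)),
        n_frames = 30L, frame_cols = 896L, noise_sd = 0
      ),
      video_path = NULL, pixel_size_um = 0.5, frame_interval_s = 1 / 30,
      geometry = list(entry_um = 100, width_um = 8, length_um = 250,
                      flow_axis = "horizontal", region1_window_um = 80,
                      entrance_margin_um = 5),
      gating_um = NULL, max_gap = 3L, min_obs = 3L, min_area_um2 = 4,
      reference_group = NULL
    )
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the [default_config()] defaults;
#' everything else keeps its default.
#'
#' @param path `.yaml`/`.yml` or `.json` file
#' @return the merged configuration list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file %s does not exist", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  utils::modifyList(default_config(), user)
}

#' Write a run configuration to YAML or JSON
#' @param config configuration list
#' @param path output path (`.yaml`/`.yml` or `.json`)
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' Hash of a configuration (for provenance and rerun identity)
#'
#' Unset (`NULL`) entries are stripped before hashing so that a config
#' written to file and read back hashes identically.
#'
#' @param config configuration list
#' @return 32-character md5 string of the canonical JSON serialisation
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(drop_nulls(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate a run configuration
#'
#' Merges with the defaults and checks the structural invariants (band
#' windows ordered, geometry consistent, margins inside windows). The
#' channel geometry is instantiated here so geometry errors surface before
#' any stage runs.
#'
#' @param config configuration list (possibly partial)
#' @return the merged, validated configuration with a `geometry` object
#'   attached at `config$strain$geometry_obj`
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  sp <- cfg$spectral
  for (nm in c("image_band", "fingerprint", "norm_window", "num_band",
               "den_band")) {
    b <- sp[[nm]]
    if (length(b) != 2L || b[1] >= b[2]) {
      stopf("config: spectral$%s must be c(lo, hi) with lo < hi", nm,
            class = "chromamech_config_error")
    }
  }
  g <- cfg$strain$geometry
  geom <- tryCatch(
    channel_geometry(entry_um = g$entry_um, width_um = g$width_um,
                     length_um = g$length_um, flow_axis = g$flow_axis,
                     region1_window_um = g$region1_window_um,
                     entrance_margin_um = g$entrance_margin_um),
    error = function(e) {
      stopf("config: invalid channel geometry: %s", conditionMessage(e),
            class = "chromamech_config_error")
    })
  if (g$entry_um - g$region1_window_um < 0) {
    stopf("config: region-1 window (%g um) extends past the frame origin (entry at %g um)",
          g$region1_window_um, g$entry_um, class = "chromamech_config_error")
  }
  cfg$strain$geometry_obj <- geom
  cfg
}

# Majority ground-truth label under each segmented cell -> planted group.
assign_groups_from_truth <- function(seg, truth) {
  n <- max(seg$labels)
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(k) {
    under <- truth$labels[seg$labels == k]
    under <- under[under > 0L]
    if (length(under) == 0L) return(NA_character_)
    truth$cells$group[as.integer(names(which.max(table(under))))]
  }, character(1))
}

write_provenance <- function(out_dir, cfg, stage_counts) {
  cfg_clean <- cfg
  cfg_clean$strain$geometry_obj <- NULL
  prov <- list(
    package = "chromamech",
    version = as.character(utils::packageVersion("chromamech")),
    seed = cfg$seed,
    config_hash = config_hash(cfg_clean),
    counts = stage_counts,
    config = cfg_clean
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Run the FTIR spectral pipeline end to end
#'
#' Simulate (or read) a hyperspectral cube, build the Amide I chemical
#' image, segment single cells, extract and preprocess per-cell spectra,
#' compute DNA-to-protein ratios, and compare treatment groups. Outputs
#' (`labels.tif`, `spectra.csv`, `ratios.csv`, `comparisons.csv`,
#' `provenance.json`) are deterministic for a fixed config and seed.
#'
#' @param config configuration list (see [default_config()])
#' @param out_dir output directory (created if missing)
#' @return invisibly, a list with the output directory, per-stage counts
#'   and the ratio/comparison tables
#' @export
run_spectral_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  sp <- cfg$spectral
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (isTRUE(sp$simulate$enabled)) {
    groups <- lapply(sp$simulate$groups, function(s) {
      default_band_models(dna_scale = s)
    })
    spec <- cube_spec(shape = sp$simulate$shape,
                      pixel_size_um = sp$simulate$pixel_size_um,
                      n_cells = sp$simulate$n_cells,
                      radius_range_um = sp$simulate$radius_range_um,
                      groups = groups, noise_sd = sp$simulate$noise_sd,
                      seed = cfg$seed)
    gen <- generate_cube(spec)
    cube <- gen$cube
    truth <- gen$truth
  } else {
    if (is.null(sp$cube_path)) {
      stopf("config: no cube_path given and simulation is disabled",
            class = "chromamech_config_error")
    }
    cube <- read_cube(sp$cube_path)
  }

  img <- chemical_image(cube, sp$image_band)
  seg <- if (isTRUE(sp$simulate$enabled) && sp$simulate$n_cells == 0L) {
    structure(list(labels = matrix(0L, dim(cube)[1], dim(cube)[2]),
                   params = list(threshold_method = "otsu")),
              class = "segmentation")
  } else {
    segment_cells(img, min_area_um2 = sp$min_area_um2,
                  max_area_um2 = sp$max_area_um2,
                  seed_spacing_um = sp$seed_spacing_um)
  }
  spectra <- extract_cell_spectra(cube, seg)
  if (!is.null(truth)) {
    spectra$group <- assign_groups_from_truth(seg, truth)
  } else if (!is.null(sp$group_map)) {
    gm <- utils::read.csv(sp$group_map)
    spectra$group <- gm$group[match(spectra$cell_id, gm$cell_id)]
  }

  ratios <- if (n_cells(spectra) > 0L) {
    proc <- preprocess_spectra(spectra, fingerprint = sp$fingerprint,
                               anchor = sp$anchor,
                               norm_window = sp$norm_window)
    compute_ratios(proc, num_band = sp$num_band, den_band = sp$den_band,
                   margin = sp$margin)
  } else {
    compute_ratios(spectra)
  }

  ref <- sp$reference_group %||% ratios$group[1]
  ok <- !is.na(ratios$ratio) & !is.na(ratios$group)
  comparisons <- if (sum(ok) > 0L && !is.null(ref) && !is.na(ref) &&
                     ref %in% ratios$group[ok] &&
                     length(unique(ratios$group[ok])) >= 2L) {
    compare_all(ratios$ratio[ok], ratios$group[ok], reference = ref,
                metric = "dna_protein_ratio")
  } else {
    message("comparison stage: nothing to compare")
    data.frame(metric = character(0), group_a = character(0),
               group_b = character(0), n_a = integer(0), n_b = integer(0),
               mean_a = numeric(0), mean_b = numeric(0), t = numeric(0),
               p = numeric(0), stars = character(0))
  }

  write_labels_tiff(seg$labels, file.path(out_dir, "labels.tif"))
  write_spectra_csv(spectra, file.path(out_dir, "spectra.csv"))
  utils::write.csv(ratios, file.path(out_dir, "ratios.csv"), row.names = FALSE)
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  counts <- list(cells_segmented = n_cells(spectra),
                 cells_flagged = sum(nzchar(ratios$qc_flag)),
                 comparisons = nrow(comparisons))
  write_provenance(out_dir, cfg, counts)
  invisible(list(out_dir = out_dir, counts = counts, ratios = ratios,
                 comparisons = comparisons))
}

# Build the per-group synthetic videos for the strain pipeline.
simulate_strain_videos <- function(cfg) {
  st <- cfg$strain
  sim <- st$simulate
  out <- list()
  gi <- 0L
  for (g in names(sim$groups)) {
    gi <- gi + 1L
    p <- sim$groups[[g]]
    n <- p$n_nuclei
    nuc <- with_seed(cfg$seed + gi, {
      minor <- stats::runif(n, p$minor_range_um[1], p$minor_range_um[2])
      nuclei_spec(
        minor_um = minor, major_um = minor * (p$aspect %||% 1.5),
        s_t = stats::rnorm(n, p$s_t_mean, p$s_t_sd),
        s_a = stats::rnorm(n, p$s_a_mean %||% 0.05, p$s_a_sd %||% 0.02),
        speed_um_s = p$speed_um_s %||% 550
      )
    })
    rows_px <- as.integer(max(128L, ceiling((40 * n + 40) / st$pixel_size_um / 2)))
    spec <- video_spec(
      nuc, geometry = st$geometry_obj,
      frame_shape = c(rows_px, sim$frame_cols),
      pixel_size_um = st$pixel_size_um, n_frames = sim$n_frames,
      frame_interval_s = st$frame_interval_s, noise_sd = sim$noise_sd,
      seed = cfg$seed + gi
    )
    out[[g]] <- generate_video(spec)
  }
  out
}

#' Run the nucleus-strain pipeline end to end
#'
#' Simulate (or read) constriction videos, detect nuclei per frame (Li
#' threshold), link trajectories with gap closing, assign channel regions,
#' compute per-nucleus transverse/axial strain and auxeticity flags, and
#' compare the small-nuclei transverse strain between groups. Outputs
#' (`strain.csv`, `tracks.csv`, `comparisons.csv`, `provenance.json`) are
#' deterministic for a fixed config and seed.
#'
#' @param config configuration list (see [default_config()])
#' @param out_dir output directory (created if missing)
#' @return invisibly, a list with the strain table, comparisons and counts
#' @export
run_strain_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  st <- cfg$strain
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- st$geometry_obj

  videos <- if (isTRUE(st$simulate$enabled)) {
    simulate_strain_videos(cfg)
  } else {
    if (is.null(st$video_path)) {
      stopf("config: no video_path given and simulation is disabled",
            class = "chromamech_config_error")
    }
    list(all = list(frames = read_video_tiff(st$video_path), truth = NULL))
  }

  all_strain <- NULL
  all_tracks <- NULL
  for (g in names(videos)) {
    obs <- detect_video(videos[[g]]$frames, st$pixel_size_um,
                        min_area_um2 = st$min_area_um2)
    if (nrow(obs) == 0L) {
      warning(sprintf("group %s: no nuclei detected", g))
      next
    }
    tracks <- link_tracks(obs, gating_um = st$gating_um, max_gap = st$max_gap)
    tracks <- assign_regions(tracks, geom)
    res <- compute_strain(tracks, geom, min_obs = st$min_obs,
                          frame_interval_s = st$frame_interval_s)
    res$group <- g
    tracks$group <- g
    all_strain <- rbind(all_strain, res)
    all_tracks <- rbind(all_tracks, tracks)
  }

  comparisons <- data.frame(metric = character(0), group_a = character(0),
                            group_b = character(0), n_a = integer(0),
                            n_b = integer(0), mean_a = numeric(0),
                            mean_b = numeric(0), t = numeric(0),
                            p = numeric(0), stars = character(0))
  small <- NULL
  if (!is.null(all_strain)) {
    tab <- strain_table(all_strain, channel_width_um = geom$width_um)
    small <- merge(tab$small_nuclei,
                   all_strain[, c("nucleus_id", "group")],
                   by = c("nucleus_id", "group"), all.x = TRUE, sort = TRUE)
    ref <- st$reference_group %||% names(videos)[1]
    counts_by_group <- table(small$group)
    usable <- names(counts_by_group)[counts_by_group >= 2L]
    if (ref %in% usable && length(usable) >= 2L) {
      sub <- small[small$group %in% usable, ]
      comparisons <- compare_all(sub$S_T, sub$group, reference = ref,
                                 metric = "S_T_small_nuclei")
    } else {
      message("comparison stage: nothing to compare")
    }
  } else {
    all_strain <- data.frame()
    warning("no nuclei tracked in any video")
  }

  utils::write.csv(all_strain, file.path(out_dir, "strain.csv"),
                   row.names = FALSE)
  if (!is.null(all_tracks)) {
    utils::write.csv(all_tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  counts <- list(
    nuclei_tracked = if (nrow(all_strain)) nrow(all_strain) else 0L,
    nuclei_excluded = if (nrow(all_strain)) {
      sum(all_strain$exclusion_reason != "")
    } else 0L,
    small_nuclei = if (!is.null(small)) nrow(small) else 0L,
    comparisons = nrow(comparisons)
  )
  write_provenance(out_dir, cfg, counts)
  invisible(list(out_dir = out_dir, strain = all_strain,
                 comparisons = comparisons, counts = counts))
}
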