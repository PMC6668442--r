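# chromamech

Single-cell readouts of chromatin state in immune cells, from two
instruments that see the same biology from different sides:

* **FTIR hyperspectral imaging** — label-free chemical imaging at
  subcellular resolution. chromamech segments absorbance cubes into single
  cells (Otsu thresholding + marker-based watershed on the Amide I chemical
  image), extracts one average spectrum per cell, and computes a
  **DNA-to-protein integrated peak ratio**: the symmetric phosphate stretch
  of the DNA backbone over the Amide II protein band,

  ratio = ∫ ν_s PO₂⁻ (1035–1070 cm⁻¹) / ∫ Amide II (1490–1580 cm⁻¹),

  each integral taken above a local baseline through the troughs flanking
  the peak, after offset-baseline correction at 1800 cm⁻¹ and normalization
  to the Amide I peak maximum (1710–1650 cm⁻¹). The ratio tracks DNA
  content and chromatin condensation at the single-cell level.

* **Deformability microfluidics** — Hoechst-stained nuclei are imaged
  translocating 8 × 8 µm², 250 µm-long constriction channels. chromamech
  detects nuclei per frame (Li thresholding), tracks them with automated
  gap closing, and computes per-nucleus **transverse and axial strain**
  from the region-averaged minor/major axes before (a, b) and inside
  (a′, b′) the channel:

  S_T = (a′ − a) / a,  S_A = (b′ − b) / b.

  A positive transverse strain — the nucleus *widening* while stretched —
  marks **auxetic** (negative-Poisson's-ratio) behaviour, expected chiefly
  in nuclei smaller than the channel width (a < 8 µm).

Both arms ship synthetic-data generators with complete ground truth
(planted masks, spectra, axes and strains), unpaired t-test group
comparisons (Welch by default), and reproducible end-to-end pipelines with
config hashing and provenance. The package is aimed at labs running either
assay who want a tested, scriptable alternative to ad-hoc notebook
analyses.

## Worked example

Simulate a two-group FTIR experiment (control vs. a chromatin-decondensed
group with 1.3× DNA-band amplitude), run the full spectral pipeline, and
compare groups:

```r
library(chromamech)

cfg <- default_config()
cfg$seed <- 42L
cfg$spectral$simulate$n_cells <- 24L
cfg$spectral$simulate$groups <- list(control = 1.0, tsa = 1.3)
cfg$spectral$reference_group <- "control"
res <- run_spectral_pipeline(cfg, "demo-out")

head(res$ratios[, c("cell_id", "group", "ratio")], 4)
#>   cell_id   group     ratio
#> 1       1     tsa 0.6474437
#> 2       2     tsa 0.6534904
#> 3       3 control 0.5045131
#> 4       4     tsa 0.6468064

res$comparisons[, c("group_a", "group_b", "n_a", "n_b", "mean_a", "mean_b", "t", "p", "stars")]
#>   group_a group_b n_a n_b    mean_a    mean_b        t            p stars
#> 1     tsa control  12  12 0.6477012 0.4996229 84.98353 2.393242e-24   ***
```

The treated group's mean ratio (0.648) sits above the control (0.500) —
the planted 1.3× DNA amplitude recovered as a highly significant per-cell
difference. `demo-out/` now holds the label image, per-cell spectra,
ratios, comparisons and a provenance JSON keyed by the config hash.

The mechanical arm, on one synthetic nucleus planted with S_T = +0.18:

```r
geom <- channel_geometry()                       # 8 um x 250 um channel
vs <- video_spec(nuclei_spec(minor_um = 6.5, major_um = 10,
                             s_t = 0.18, s_a = 0.08, y_um = 32),
                 geom, n_frames = 40)
gen <- generate_video(vs)
obs <- detect_video(gen$frames, pixel_size_um = 0.5)
tracks <- assign_regions(link_tracks(obs), geom)
compute_strain(tracks, geom)[, c("nucleus_id", "n_region1", "n_region2",
                                 "a_um", "a_prime_um", "S_T",
                                 "auxetic", "small_nucleus")]
#>   nucleus_id n_region1 n_region2     a_um a_prime_um      S_T auxetic small_nucleus
#> 1          1         4        13 6.403317   7.583371 0.184288    TRUE          TRUE
```

The planted strain (0.18) is recovered as 0.184 from 4 pre-channel and 13
in-channel observations; the nucleus is correctly flagged auxetic and
smaller than the channel.

A thin CLI wraps the same functions (`inst/exec/chromamech`), with verbs
`simulate-cube`, `simulate-video`, `segment-cube`, `ratios`, `strain`,
`compare` and `run`.

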