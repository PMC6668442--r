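---
title: "Methods: single-cell FTIR peak ratios and microfluidic nuclear strain"
author: "chromamech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell FTIR peak ratios and microfluidic nuclear strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromamech)
```

chromamech implements two complementary single-cell readouts of chromatin
state in immune cells, together with synthetic-data generators that make
every stage testable against planted ground truth:

1. a **spectral arm** that turns FTIR hyperspectral absorbance images into a
   per-cell DNA-to-protein integrated peak ratio, and
2. a **mechanical arm** that turns fluorescence videos of Hoechst-stained
   nuclei translocating a microfluidic constriction channel into per-nucleus
   transverse/axial strain and an auxeticity classification.

This vignette documents the models, the tunable parameters and their
defaults, the design decisions taken where several constructions were
reasonable, and what the synthetic benchmarks do and do not demonstrate
about real instrument data.

## The spectral arm

### Model

An FTIR hyperspectral cube is a three-dimensional dataset: two spatial axes
and one wavenumber axis. Absorbance at each wavenumber reports local
chemical composition via the Beer–Lambert law. All analysis is restricted to
the fingerprint region, 1800–1000 cm⁻¹, which carries the protein Amide I
(~1655 cm⁻¹) and Amide II (~1545 cm⁻¹) bands, lipid CH₂/CH₃ bending
(~1455 cm⁻¹), and the phosphate stretches of the DNA backbone — the
symmetric stretch ν_s PO₂⁻ being the DNA-specific signal integrated at
1070–1035 cm⁻¹.

The per-cell metric is

$$
\mathrm{ratio} \;=\;
\frac{\int \nu_s\,\mathrm{PO}_2^-\ (1035\text{–}1070\ \mathrm{cm}^{-1})}
     {\int \mathrm{Amide\ II}\ (1490\text{–}1580\ \mathrm{cm}^{-1})},
$$

with each integral taken above a local straight baseline drawn through the
absorbance troughs on either side of the peak. Amide II, not Amide I, is the
protein denominator because Amide I can carry a contribution from the water
bending mode.

### Segmentation

Cells are located on a chemical image — the per-pixel *peak maximum* of the
Amide I band over 1625–1675 cm⁻¹ (the maximum, not the integral, is the
default because cell detection keys on band intensity; both reductions are
available). Segmentation proceeds as:

* global Otsu threshold on the chemical image (degenerate, constant images
  are an error);
* Euclidean distance transform of the foreground;
* marker-based watershed: markers are local maxima of the distance map, and
  maxima closer than the *seed spacing* (default 8 µm, about one cell
  diameter for the 10–15 µm B cells the defaults target) are fused into one
  marker before seeded region growing partitions the foreground
  (`EBImage::propagate`). Every foreground pixel belongs to exactly one
  label; ridge pixels are never double-counted.
* an area filter, 20–500 µm² by default, removing debris and unsplit clumps.
  The implementation relies on this filter alone; there is no manual
  exclusion step.

One average spectrum per cell is then the unweighted arithmetic mean over
that label's pixels at each wavenumber.

### Preprocessing and integration

Each cell spectrum passes through an ordered chain, recorded in the object's
provenance:

1. **crop** to the fingerprint region (1000–1800 cm⁻¹);
2. **offset baseline**: the absorbance at the 1800 cm⁻¹ anchor — a region
   with no cellular bands — is subtracted (linear interpolation when the
   anchor falls between grid points);
3. **Amide I normalization**: division by the spectrum's maximum over
   1650–1710 cm⁻¹, cancelling optical thickness and density. Cells whose
   window maximum is not positive cannot be normalized and are flagged and
   excluded downstream rather than silently dropped.

Two Amide I windows coexist deliberately: 1625–1675 cm⁻¹ for imaging and
1650–1710 cm⁻¹ for normalization. Both are configurable; they serve
different purposes (detection contrast vs. a stable normalization maximum)
and are not unified.

`integrate_peak()` searches for the left trough (absorbance minimum) within
`margin` (default 30 cm⁻¹) below the band's lower edge and the right trough
within `margin` above its upper edge, draws the chord through the two trough
points, and integrates the spectrum above that chord by the trapezoid rule.
Two interpretive decisions are worth stating explicitly:

* **Integration limits are trough-to-trough**, not the nominal band edges;
  the band edges only delimit the trough search. This follows directly from
  defining the baseline as the chord through the troughs.
* **Below-baseline area is clipped to zero.** An integrated peak intensity
  is non-negative by construction; allowing negative lobes to cancel would
  make the ratio sign-unstable for weak peaks. The choice is recorded with
  the result, and troughs that land on a search-window edge are flagged.

The 30 cm⁻¹ margin is wide enough to reach the inter-band minima flanking
both analysis windows on typical cell spectra, and narrow enough not to
cross into the neighbouring bands.

Two structural properties follow from this construction and are enforced by
tests: the ratio is invariant to rescaling the raw spectrum (normalization
cancels any positive factor), and on the synthetic band model it is
monotonically increasing in the DNA-band amplitude.

## The mechanical arm

### Geometry and regions

The default channel geometry matches the assay the pipeline was built for:
square channels 8 µm wide and 250 µm long connecting two reservoirs, cells
driven at a roughly constant ~0.55 mm/s and imaged at 30 frames/s. Flow is
internally normalized to the +x direction.

Each tracked observation is assigned to

* **region 1** — a window upstream of the channel entrance (default 80 µm),
  excluding an entrance margin (default 5 µm);
* **region 2** — the channel interior, excluding the margin inside the
  entrance and exit; or
* **excluded** otherwise.

The region-1 window default deserves a note. At 0.55 mm/s and 30 frames/s a
nucleus advances ≈18 µm per frame, and the inclusion rule demands at least
3 observations per region (a mean of fewer noisy frames is dominated by
detection jitter). A 50 µm window would deliver only ~2 pre-channel
observations and exclude essentially every nucleus at the design speed, so
the default window is 80 µm, giving 3–4 region-1 frames per nucleus. Both
the window and margin are configurable.

### Detection, tracking, strain

Nuclei are segmented per frame by **Li minimum-cross-entropy thresholding**
(implemented as the standard fixed-point iteration on class means;
cross-checked in the tests against reference values from an independent
implementation), labelled by connected components, and measured as
**intensity-weighted moment-equivalent ellipses**: axis lengths are
4·√(eigenvalue) of the weighted covariance of pixel centres (plus the 1/12
per-pixel variance), which is exact for a solid ellipse. Intensity weighting
rather than a binary mask suppresses the jagged-boundary noise of small
(~10 px) objects; bounding boxes and contour fits were rejected as,
respectively, rotation-sensitive and unstable at this size.

Tracking is greedy nearest-neighbour assignment between consecutive frames
within a gating distance, by default 1.5× the mean frame-to-frame
displacement estimated from the data itself. Fragmented trajectories are
stitched automatically: a fragment starting within 3 frames (configurable)
and within gating × gap of another fragment's end is merged, with the merge
recorded. Automating the stitching removes the only human step from the
analysis chain; distance ties break deterministically toward the smaller
track id.

For every trajectory with ≥3 observations in each region, the region means
of the minor/major axes (a, b pre-channel; a′, b′ in-channel) give

$$
S_T = \frac{a' - a}{a}, \qquad S_A = \frac{b' - b}{b},
$$

with `auxetic = (S_T > 0)` — the nucleus widens transversally while being
stretched — and `small nucleus = (a < channel width)`, the subpopulation
that can expand inside the channel and in which auxetic behaviour is
expected. Trajectories failing the observation minimum are reported with an
exclusion reason, never dropped silently. Per-trajectory speed (mean
displacement per frame interval) is reported because the absence of a
speed–auxeticity correlation is a useful control, though speed plays no
role in the strain itself.

### Statistics

Group comparisons are two-sided unpaired t-tests. Welch's unequal-variance
form is the default — it is never anticonservative under variance
heterogeneity between treatment groups — with the pooled-variance Student
form available by flag for exact reproduction of analyses that used it.
Significance is reported as `***` (p ≤ 0.001), `*` (p ≤ 0.05) or `ns`; no
multiple-testing correction is applied by default (a Bonferroni option
exists) because the per-cell scatter figures this mirrors report raw stars.
The default unit of analysis is the cell; replicate labels are carried so a
replicate-mean analysis can be run instead.

## Synthetic data: what it emulates, what it does not

### Cubes

`generate_cube()` plants non-overlapping disks in the frame and gives every
in-cell voxel its treatment group's spectrum: a sum of Gaussian bands
(Amide I 1655, Amide II 1545, CH₂/CH₃ 1455, ν_as PO₂⁻ 1240, ν_s PO₂⁻
1052 cm⁻¹) plus i.i.d. Gaussian voxel noise. Three generator conventions
matter:

* **Band shape is Gaussian** with FWHM parameterisation — the simplest
  symmetric line shape, sufficient to exercise the integration logic, which
  never assumes a shape.
* **The DNA band is centred at 1052 cm⁻¹**, inside the 1035–1070 cm⁻¹
  window the assay integrates: the assay defines that window *as* the
  ν_s PO₂⁻ peak, so the simulator places the band it is meant to represent
  inside it.
* **Amplitudes are uncalibrated free parameters** (defaults: 1.0, 0.6,
  0.25, 0.22, 0.30 relative to Amide I). Absolute cellular absorbances
  depend on thickness and instrument; since the ratio normalizes them away,
  only relative amplitudes matter to the pipeline.

The default grid is 1000–1800 cm⁻¹ at the instrument-typical 4 cm⁻¹ step:
every analysis stage operates in the fingerprint region, so simulating the
full acquisition range would only inflate memory. Pixels default to
1.1 × 1.1 µm², cell radii to 5–7.5 µm (10–15 µm diameter B cells).

`simulate_cell_spectra()` bypasses imaging and draws per-cell spectra
directly. Its `noise_sd` is the *voxel-level* absorbance noise — the same
quantity as in the cube generator — and the per-cell spectrum receives
`noise_sd / sqrt(pixels_per_cell)` (default 100 pixels, a 12.5 µm cell at
1.1 µm pixels), because in the full pipeline a cell's spectrum is the
average over its segmented pixels. With voxel noise at 10% of the Amide I
amplitude, three groups of 50 cells whose DNA-band amplitude is scaled
×0.7 / ×1.0 / ×1.4 reproduce both the expected ordering of group means and
treated-vs-control significance at α = 0.001 in ≥95% of seeded replicates.

Not emulated: interferometry, atmospheric water-vapour lines, Mie and
resonant-Mie scattering, detector drift, mosaic tiling. Passing benchmarks
therefore demonstrate the correctness of segmentation, extraction and the
ratio algebra under controlled noise — not robustness to scattering
artefacts, which real cubes may require dedicated correction for.

### Videos

`generate_video()` renders each nucleus as a filled ellipse translating at
constant speed, with intensity falling off as a super-Gaussian
`exp(-(r/r0)^s)` in normalized radius. The edge order (default `s = 40`,
a sub-pixel transition at 0.5 µm pixels, about half a high-NA point-spread
width) is fixed so that Li thresholding cuts the profile within ~2.5% of
the nominal boundary: the rendered edge is the *definition* of the planted
axis, and a controlled edge keeps the planted axes and the detected
moment-equivalent axes consistent to better than 0.3 µm.

Axes switch between the pre-channel values and the planted strained values
a·(1+S_T), b·(1+S_A) over a two-frame linear ramp at the channel entrance
(and back at the exit) — an instantaneous shape jump would be unphysical.
At the design speed the ramp extends ~36 µm into the channel, beyond the
5 µm entrance margin, so one or two partially-deformed frames enter the
region-2 mean; the resulting bias on S_T is ≈ S_T/12 (≈0.02 at S_T = 0.25),
well inside the ±0.05 end-to-end recovery band the tests enforce. The
ground-truth table therefore carries both the per-frame instantaneous axes
and the plateau axes, and the exactness of the strain formulas is asserted
against the plateau values.

Not emulated: photobleaching, motion blur, cytoplasm or cell-body
fluorescence, out-of-focus light. Noiseless benchmarks demonstrate the
geometry, tracking and strain algebra; the fluorescence noise knob exists
but detection robustness at low SNR is not a claim this package makes.

## Numerical conventions and degenerate inputs

* Coordinates are row-major, 0-based pixel indices; physical position =
  (index + 0.5) × pixel size. Wavenumber axes are stored ascending; readers
  reverse descending input consistently (ENVI float32 band-sequential pairs
  and a lossless RDS array archive are both supported).
* Trough positions take the first minimum on ties (lowest wavenumber);
  tracking ties break toward the smaller track id; both are deterministic.
* Constant images raise degenerate-threshold errors; blank frames return
  empty observation tables (not errors); empty segmentations yield empty
  spectra lists and empty ratio tables; zero-variance t-test inputs are
  errors.
* All generators take integer seeds and restore the caller's RNG state;
  identical spec + seed gives bit-identical output, and pipeline runs with
  the same config hash produce byte-identical CSV/JSON outputs (provenance
  deliberately contains no timestamps).

## Problem sizes used by the test and acceptance suites

The shipped suites exercise: cubes up to 160 × 160 px × 201 bands with up to
50 planted cells (50 seeded segmentation-recovery runs; 20 overlap-pair
fixtures); masked-mean oracles on 20 random 64 × 64 × 400 cubes; the
three-group ratio study at 100 replicates × 150 cells; four end-to-end
videos of 40 frames at 896 × 128 px; and exhaustive permutation oracles at
n ≤ 8 (the 3-vs-3 case is excluded from rejection fixtures because its
smallest attainable two-sided permutation p is 0.1). These sizes were chosen
so the full suite runs in well under a minute on one core while still
crossing every scale the algorithms care about.

## Known limitations

* No scattering/atmospheric correction and no exploratory spectral analysis
  (PCA/HCA, curve deconvolution, DNA-conformation markers) — the spectral
  arm computes exactly one calibrated metric per cell.
* Watershed splitting relies on distance-map geometry; heavily clumped
  monolayers beyond pairwise contact are only handled through the area
  filter.
* The auxeticity proxy is the sign of S_T; no Poisson's ratio is estimated
  and no pressure/flow modelling is attempted.
* Whether bounding-box or ellipse axes, and which t-test variant, best match
  any particular upstream analysis cannot be inferred from data alone; both
  choices here (equivalent ellipse, Welch) are stated defaults with the
  alternatives exposed as options.
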