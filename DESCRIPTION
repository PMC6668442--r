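Package: chromamech
Title: Single-Cell FTIR Spectroscopy and Microfluidic Nuclear Strain Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two single-cell assays of chromatin state in immune
    cells. The first arm segments FTIR hyperspectral absorbance images into
    single cells (Otsu thresholding plus watershed), extracts per-cell average
    spectra, and computes a trough-baselined integrated DNA-to-protein peak
    ratio (symmetric phosphate stretching over Amide II) after offset baseline
    correction and Amide I normalization. The second arm detects Hoechst-stained
    nuclei in microfluidic constriction videos (Li thresholding), tracks them
    between frames with automated gap closing, and computes transverse and
    axial nuclear strain with an auxeticity classification. Both arms ship
    synthetic-data generators with full ground truth, group-comparison
    statistics (unpaired t-tests), and reproducible end-to-end pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
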