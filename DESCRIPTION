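Package: vesselmap
Title: Single-Vessel Amyloid Analysis for Hyperspectral LCO Microscopy and
    MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for chemical and structural characterization of cerebral
    amyloid angiopathy (CAA) at single-vessel resolution. Implements automated
    vessel segmentation and emission-spectrum extraction from hyperspectral
    images of luminescent conjugated oligothiophene (LCO) stained tissue,
    including the 500/580 nm emission-ratio maturity statistic; a MALDI mass
    spectrometry imaging (MSI) quantification chain (total-ion-current
    normalization, bisecting k-means spatial segmentation, peak detection and
    binning on average spectra, area-under-curve integration, relative and
    subgroup quantification, and single-pixel signal correlation); a
    proteoform toolkit for ABri, ADan, and amyloid-beta peptides (theoretical
    monoisotopic masses with pyroglutamate and disulfide deltas, hydrophobic
    fractions, truncation subgroup classification); and seed-deterministic
    synthetic-data generators with analytic ground truth for both modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    MASS,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
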