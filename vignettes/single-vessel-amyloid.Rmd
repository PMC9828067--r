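---
title: "Single-vessel amyloid analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-vessel amyloid analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmap)
```

# Scope

`vesselmap` analyzes cerebral amyloid angiopathy (CAA) at single-vessel
resolution across two imaging modalities: hyperspectral microscopy of
luminescent conjugated oligothiophene (LCO) double stains, and MALDI mass
spectrometry imaging (MSI) of amyloid proteoforms. A proteoform module
covers the ABri, ADan and amyloid-beta (Aβ) peptide families, and
synthetic-data generators provide ground-truthed inputs for every stage.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, what the generators do and do not
emulate, and the package's known limitations.

# Proteoform model

A proteoform is a residue span `[start, end]` of a precursor's amyloid
region — ABri and ADan are the 34-residue amyloidogenic peptides released
from mutant BRI2 (identical over residues 1–22, divergent C-termini); the
Aβ region is residues 1–42 of the APP-derived peptide — optionally
carrying an N-terminal pyroglutamate (pE) and intramolecular disulfide
bonds. Construction enforces the biochemical invariants: the span must lie
inside the region, pE requires Glu or Gln at the new N-terminus, and the
disulfide count cannot exceed `floor(nCys / 2)` over the spanned sequence
(ABri/ADan contain two cysteines, Aβ none).

**Masses.** `monoisotopic_mass` sums residue monoisotopic masses plus one
water; pE formed from Glu subtracts one water (18.010565 Da), from Gln one
ammonia (17.026549 Da); each disulfide subtracts two hydrogens
(2 × 1.007825 Da). `species_mz` adds one proton for the `[M+H]+` ions
observed in linear-TOF MALDI. A concatenation oracle (mass of `s1 + s2`
equals the sum of parts minus one water) pins the implementation in the
tests.

**Hydrophobic fraction.** The statistic is 100 × (residues in the
hydrophobic class) / length, reported to one decimal with round-half-away
-from-zero. The class {Ala, Phe, Ile, Leu, Met, Val, Trp} — excluding Cys,
Gly and Tyr — was fixed *before* the main build by validating candidate
classes against the full published truncation series (ABri1-34 38.2 %,
ABri1-29 37.9 %, ADan1-34 41.2 %, ADan1-29 48.3 %, ADan1-28 50 %, Aβ1-40
42.5 %, Aβ1-42 45.2 %); it reproduces all of them exactly under integer
residue counting. The one open point: ADan1-33 computes to 14/33 = 42.4 %
while ~42.2 % has been reported for it, suggesting the original calculator
may use fractional residue weights; we keep integer counting (it is the
only rule consistent with all other printed values) and exclude ADan1-33
from golden-value checks.

**Subgroups.** Species are classified into the four non-exclusive groups
used for fractional-content summaries: *full-length* (start 1, canonical
C-terminus — 34 for ABri/ADan, 42 for Aβ — and no pE), *C-truncated*
(shorter C-terminus), *N-truncated* (start > 1), *pyroglutamate*. A
position-1 pE species counts toward the N-truncated group by default: pE
is an N-terminal modification, and population summaries in which pE1
species dominate are only coherent under this convention. The switch
`pyroglu_counts_n_truncated = FALSE` selects the stricter reading.

# Hyperspectral LCO pipeline

The input is a rows × cols × 32-channel emission cube with a wavelength
axis covering 405–750 nm (lambda-mode spectral detector; ~11 nm channel
spacing) and pixel size around 300 nm. The pipeline
(`run_lco_pipeline`) chains:

1. **Maximum-intensity projection** along the spectral axis.
2. **Background subtraction**: the background is a Gaussian blur of the
   projection with a large sigma (default 200 px) and is subtracted;
   negative residuals are kept (clamping would shift the threshold
   histogram; a `clamp_negative` switch exists). The blur is an exact
   separable convolution with *reflective* padding — circular or zero
   padding darkens the borders at this sigma and would segment the image
   edge.
3. **Otsu threshold** on a 256 equal-width-bin histogram over the observed
   range (signed values allowed). The threshold is accepted only if
   Otsu's effectiveness metric — between-class variance over total
   variance — exceeds `min_effectiveness` (default 0.7). The optimal
   split of pure Gaussian noise scores ≈ 0.64 analytically (and
   measured), vessel-bearing images ≥ 0.84, so the gate cleanly rejects
   foreground-free fields instead of thresholding noise.
4. **Binary closing** with a disk of radius 5 px, which fills vessel
   lumens and small mask defects. The image is padded before closing so
   border behavior is well-defined; closing is idempotent.
5. **Connected components** with 8-connectivity; components smaller than
   `min_roi_pixels` (default 50 px at 300 nm pixel size, i.e. vessels
   below ~2 µm² are discarded as specks) are dropped. Each ROI carries
   the channel-wise mean spectrum of its pixels; the full-field average
   spectrum is returned for comparison.
6. **Emission ratio**: intensity at the channel nearest 500 nm over the
   channel nearest 580 nm on the ROI-average spectrum. Nearest-channel
   lookup (no interpolation) matches the coarse channel spacing; an
   interpolating mode exists behind a flag. The ratio is invariant to any
   scalar rescaling of the spectrum, so whether average spectra are
   max-normalized for plotting (`normalize_spectrum`) does not affect it.

# MALDI-MSI quantification chain

The input is per-pixel centroid mass spectra on a regular 2-D grid
(10 µm pitch for conformant data). Processing:

* **TIC normalization** rescales each pixel to the dataset-mean total ion
  current (preserving the global intensity scale rather than normalizing
  to 1; configurable). Zero-TIC pixels are dropped with a warning.
* **Average spectrum** on a regular 0.5 Da grid; **peak detection** finds
  local maxima above `snr` (default 3) times a robust noise level —
  1.4826 × median |first difference| / √2, insensitive to the peaks
  themselves — and additionally requires the same margin as *prominence*
  over the flanking local minima, which rejects noise ripples riding on
  peak slopes. Bin edges sit at the flanking minima, truncated at the
  half-distance to neighbouring peaks and capped at ±0.35 % of the center
  m/z (≈ linear-TOF peak width near 4 kDa), so neighbouring proteoforms
  ~2 Da apart never share a bin.
* **Annotation** matches bins to theoretical `[M+H]+` masses one-to-one by
  increasing m/z distance (each species annotates only its nearest
  candidate bin; a chance matrix peak close to a species mass cannot
  duplicate an annotation).
* **Segmentation**: pixels are represented by their bin-integrated
  intensity vectors and clustered by bisecting k-means — repeatedly
  2-means-splitting the cluster with the largest within-cluster sum of
  squares (10 restarts per bisection, fixed seed, deterministic) until
  `n_leaf_clusters` leaves (default 2). The leaf with the highest mean
  summed signal over species-annotated bins is the vessel cluster;
  8-connected components of it (≥ 5 px) are the vessel ROIs.
* **Relative quantification** divides each species' per-ROI integrated
  intensity by the full-length reference peptide (ABri1-34, ADan1-34 or
  Aβ1-40 depending on cohort); means ± SD are reported across vessels.
* **Subgroup fractions** are intensity-weighted percentages per ROI,
  averaged across ROIs; the groups are non-exclusive, so columns need not
  sum to 100.
* **Fractional contribution and coverage** of a species subset (typically
  all Aβ): the subset's share of total amyloid signal over vessel pixels,
  and the fraction of vessel pixels whose summed subset intensity exceeds
  the off-vessel background mean + 2 SD (the `coverage_k` rule; no
  published rule exists, so the threshold is documented and
  configurable). These two statistics are computed on *raw* (pre-
  normalization) intensities: TIC normalization rescales pixels inversely
  to their total content, which systematically compresses the apparent
  share of a species confined to a sub-region of the vessel wall (we
  measured 3.8 % recovered for a planted 4.6 % share on normalized data,
  4.6 % on raw), whereas multiplicative acquisition gain is content-
  independent and cancels in a ratio of sums.
* **SPSC** (single-pixel signal correlation): pairwise Pearson correlation
  (Spearman behind a flag) of species intensities across masked pixels,
  computed by direct covariance/variance algebra. Zero-variance species
  get `NA` rows/columns — undefined, not zero.

# Synthetic data

The generators make every stage testable with analytic ground truth;
truth values are derived from the configuration, never re-measured from
the generated arrays.

**LCO** (`generate_lco_image`): annular vessels (CAA is vascular-wall
deposition; the lumen hole exercises the closing step) with outer radius
9–13 px, lumen 3 px, on a flat background (2 % of the vessel amplitude)
with per-channel Gaussian noise (default sd 10 % of amplitude). Each
vessel's pixels carry `w·q + (1−w)·h` endmember mixtures — unit-peak
Gaussians at 500 and 580 nm (sd 30 nm) — sampled at the 32 channel
centers. Planted 500/580 ratios (default uniform in [0.5, 2]) are
converted to weights by the analytic inverse of the ratio of the full
planted pixel spectrum (mixture *plus* background) at the two ratio
channels; that spectrum is what a perfect extractor recovers, so the
truth accounts for the background term. Ground-truth vessel footprints
include the lumen (the closing step fills it by design).

**MSI** (`generate_msi_dataset`): annular vessels (outer radius 4–6 px,
lumen 1.5 px at 10 µm pitch — 80–120 µm vessels, 75 per region as
analyzed per cohort) on a 260 × 260 grid. Species intensities are
log-normal (pixel-level sd 0.5 on the log scale) with a configurable
latent cross-species correlation (default: blocks by precursor, Aβ split
by C-terminus, r = 0.8 within / 0.1 across), scaled per vessel
(log-normal sd 0.3) and per pixel by a multiplicative TIC gain field
(log-normal sd 0.3) that normalization must remove. Unassigned matrix
peaks (6 per pixel) provide background TIC. For the FDD preset, Aβ
species are confined to a contiguous patch covering 13.3 % of each
vessel's pixels and rescaled analytically so Aβ carries 4.6 % of the
expected total amyloid signal. Preset abundance profiles were chosen once,
analytically, to embody the reported composition patterns of the three
cohorts — e.g. for FDD: ADan1pE-33 dominant, ADan full-length 6.5 %,
C-truncated 69 %, N-truncated 87.5 %, pE 63 %; Aβ full-length 14.5 %,
C-truncated 74 %, N-truncated 71 %, pE 30 % — so recovery tests compare
against a realistic composition.

**What the generators do not emulate** — and hence what passing tests do
*not* establish about real data: TOF peak shapes and isotope envelopes
(centroid spikes by default; profile mode exists only to exercise
trapezoidal integration), mass calibration drift, detector saturation,
ionization-efficiency differences between proteoforms, optics point-spread
and chromatic effects in the hyperspectral channel, autofluorescence
spectra, partial-volume vessel boundaries, and cross-modality registration
(performed visually in practice and out of scope here). Recovery results
therefore demonstrate correctness of the computational chain under the
stated noise models, not instrument-level accuracy.

# Numerical choices and degenerate inputs

* All stochastic components (generators, k-means restarts) are driven by
  explicit integer seeds; identical inputs give bit-identical outputs.
* Otsu on a constant image raises a "degenerate histogram" error; inside
  the pipeline this (like a sub-gate effectiveness) yields an empty ROI
  list rather than an error.
* Argmax ties (Otsu bin, nearest channel, best-overlap matching) resolve
  to the first maximum, making tie-breaks deterministic.
* The ratio statistic errors on a zero denominator ("no 580 nm signal")
  instead of returning infinity.
* `tic_normalize` drops zero-TIC pixels loudly; an all-zero dataset is an
  error. Readers never repair silently: unsorted m/z axes are sorted with
  a warning, duplicate coordinates are an error.
* Component labelling is renumbered in first-pixel order, so labels do not
  depend on igraph internals.

# Problem sizes

The test suite and the acceptance script run, by choice, at the study's
own scale where that is cheap — 50-vessel hyperspectral images
(512 × 512), 75-vessel MSI grids (260 × 260, 16 species), 500-pixel SPSC
masks, 100-image Otsu oracle sweeps — and at reduced scale for
property-style checks (e.g. 300 noise spectra for the false-peak rate).
The full suite completes in well under a minute on one CPU.

# Interfaces

The package's surface is its exported functions plus
`scripts/acceptance.R`; file exchange uses multi-page TIFF with a JSON
wavelength sidecar for hyperspectral cubes and a plain-text long-format
CSV (+ JSON metadata) for MSI datasets. No imzML reader is bundled: the
portable text format round-trips losslessly and keeps the package free of
binary-format dependencies; conversion from imzML is a one-liner in any
environment with an imzML parser. Pixel coordinates are 0-based, x right,
y down; CSV output is comma-separated UTF-8 with "." decimals and
mandatory headers. `write_report` emits per-table CSVs plus a JSON
manifest (seed, config echo, package version, row counts) sufficient to
re-run bit-identically.

# Known limitations

* Quantification compares species within a spectrum; differential
  ionization/desorption between proteoforms is not modelled, matching the
  practice of reporting intensities relative to the dominant full-length
  peptide.
* The bisecting k-means feature space is unscaled TIC-normalized bin
  intensities; heavily skewed intensity distributions may warrant a
  variance-stabilizing transform that the package does not apply.
* The segmentation quality gate is calibrated for fields that are either
  vessel-bearing or empty; images dominated by diffuse parenchymal signal
  were not a design target.
* Profile-mode (continuous) MSI support is limited to trapezoidal bin
  integration; no baseline subtraction or isotope deconvolution is
  performed.
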