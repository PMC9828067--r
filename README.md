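# vesselmap

Single-vessel amyloid analysis for hyperspectral LCO microscopy and MALDI
mass spectrometry imaging.

## The problem

Cerebral amyloid angiopathy (CAA) is the deposition of amyloid peptides in
the walls of cerebral and leptomeningeal blood vessels. In the familial
British and Danish dementias (FBD, FDD) the deposits are built from the
BRI2-derived peptides ABri and ADan; in sporadic CAA they are dominated by
APP-derived amyloid-beta (Aβ). Each peptide occurs as many *proteoforms* —
truncation variants, N-terminal pyroglutamate (pE) modifications,
disulfide-bridged forms — and both the structural maturity of the deposits
and their proteoform composition can be resolved at the level of
individual vessels by combining two imaging modalities on adjacent
sections:

* **Hyperspectral microscopy of LCO double stains.** The luminescent
  conjugated oligothiophenes q-FTAA (emission maximum near 500 nm, binds
  mature fibrils) and h-FTAA (near 580 nm, binds immature aggregates)
  report aggregate maturity through the per-vessel emission-intensity
  ratio `R = I(500 nm) / I(580 nm)`.
* **MALDI-MSI.** One mass spectrum per 10 µm pixel resolves the individual
  proteoforms as `[M+H]+` peaks, giving per-vessel relative abundances,
  truncation subgroup fractions, and pixel-level co-localization
  statistics.

`vesselmap` implements both analysis chains as a tested R package,
together with a proteoform toolkit (theoretical monoisotopic masses with
pyroglutamate/disulfide deltas, hydrophobic fractions, subgroup
classification) and seed-deterministic synthetic-data generators with
analytic ground truth, so that every stage is testable without patient
data.

## Core statistics

* **LCO pipeline** (`run_lco_pipeline`): maximum-intensity projection
  along the spectral axis → background subtraction (Gaussian blur,
  σ = 200 px, reflective padding) → Otsu threshold (256-bin histogram,
  with an effectiveness quality gate) → binary closing (disk, r = 5 px) →
  8-connected components → per-ROI average emission spectra and the
  500/580 nm ratio.
* **MSI pipeline** (`run_msi_pipeline`): TIC normalization to the
  dataset-mean total ion current → peak and peak-width detection on the
  average spectrum (robust MAD noise, SNR ≥ 3, prominence criterion) →
  non-overlapping integration bins annotated with proteoform species →
  bisecting k-means spatial segmentation → vessel ROIs → relative
  quantification against the full-length reference peptide (ABri1-34,
  ADan1-34 or Aβ1-40), subgroup fractions (full-length / C-truncated /
  N-truncated / pE), fractional Aβ signal and area coverage, and the
  single-pixel signal correlation (SPSC) matrix.
* **Proteoforms**: `monoisotopic_mass` (residue masses + H2O, −18.010565
  Da per pE from Glu, −2 × 1.007825 Da per disulfide),
  `hydrophobic_fraction` (percentage of residues in {A, F, I, L, M, V,
  W}), `classify_subgroups`.

## Worked example

```r
library(vesselmap)

# a synthetic LCO acquisition: 5 annular vessels with planted 500/580 ratios
sim <- generate_lco_image(lco_sim_config(image_size = c(256, 256),
                                         n_vessels = 5, seed = 11))
res <- run_lco_pipeline(sim$image)
res
#> lco_result: 5 vessel ROI(s), Otsu threshold 233.1
#>   label n_pixels centroid_row centroid_col ratio_500_580
#> 1     1      516     41.30620     84.14535     0.9395800
#> 2     2      446    144.04036    124.61211     1.2485191
#> 3     3      334     56.29042    124.32335     0.5267396
#> 4     4      357     65.85994    194.47059     0.5855316
#> 5     5      370    214.40270    202.59730     0.4831921
```

All five vessels are segmented; each `ratio_500_580` is the emission
intensity at the channel nearest 500 nm over that nearest 580 nm on the
ROI-average spectrum — values above 1 indicate q-FTAA-dominated (mature)
amyloid. Matched against the generator's analytic truth, the recovered
ratios are within a few percent (e.g. planted 0.916 → recovered 0.940).

```r
hydrophobic_fraction(get_sequence("ABri", 1, 34))   # 38.2 (%)
hydrophobic_fraction(get_sequence("ADan", 1, 34))   # 41.2 (%)

proteoform("ADan", 1, 33, pyroglu = TRUE, disulfides = 1)
#> ADan1pE-33: EASNCFAIRHFENKFAVETLICFNLFLNSQEKH [1 S-S]
monoisotopic_mass(proteoform("ADan", 1, 33, pyroglu = TRUE, disulfides = 1))
#> 3878.866
```

Full-length ADan is more hydrophobic than full-length ABri, and its
hydrophobicity rises further with C-terminal truncation — the property the
hydrophobic-fraction statistic quantifies across the truncation series.

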